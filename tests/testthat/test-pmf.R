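grid9 <- seq(9, 25, by = 2)

test_that("zero mean forces integrate to an identically zero PMF", {
  p <- integrate_pmf(data.frame(D = grid9, mean_force = 0, sem = 0))
  expect_equal(p$W, rep(0, 9))
  expect_equal(p$sigma_W, rep(0, 9))
  expect_equal(p$anchor_D, 25)
})

test_that("constant and linear mean forces are integrated exactly", {
  p <- integrate_pmf(data.frame(D = grid9, mean_force = 1, sem = 0))
  expect_equal(p$W, 25 - grid9)          # W(D) = c*(Dmax - D), c = 1
  expect_equal(p$W[1], 16)

  # trapezoid is exact for a linear integrand: F = a + b*D
  f <- 0.3 - 0.05 * grid9
  p2 <- integrate_pmf(data.frame(D = grid9, mean_force = f, sem = 0))
  W_exact <- vapply(grid9, function(d)
    0.3 * (25 - d) - 0.05 / 2 * (25^2 - d^2), numeric(1))
  expect_equal(p2$W, W_exact)
})

test_that("a tabulated landscape is recovered from finely sampled forces", {
  ls <- gaussian_well_landscape()
  D <- seq(9, 25, by = 0.1)
  p <- integrate_pmf(data.frame(D = D, mean_force = true_mean_force(ls, D)))
  expect_lt(max(abs(p$W - landscape_energy(ls, D))), 0.05)
})

test_that("integration is linear in the mean forces", {
  set.seed(8)
  f <- rnorm(9); g <- rnorm(9)
  W <- function(x) integrate_pmf(data.frame(D = grid9, mean_force = x))$W
  expect_equal(W(2 * f + 3 * g), 2 * W(f) + 3 * W(g))
})

test_that("recovery error shrinks as O(h^2) under grid refinement", {
  ls <- gaussian_well_landscape()
  err <- vapply(c(2, 1, 0.5), function(h) {
    D <- seq(9, 25, by = h)
    p <- integrate_pmf(data.frame(D = D, mean_force = true_mean_force(ls, D)))
    max(abs(p$W - landscape_energy(ls, D)))
  }, numeric(1))
  # halving h should shrink the max error roughly 4-fold
  expect_gt(err[1] / err[2], 2.5)
  expect_gt(err[2] / err[3], 2.5)
})

test_that("uncertainty propagation reproduces the trapezoid-weight closed form", {
  p <- integrate_pmf(data.frame(D = grid9, mean_force = 0, sem = 0.4))
  # uniform sem s on a uniform grid: sigma_W(9)^2 = s^2 (1 + 7*4 + 1) (h/2)^2
  expect_equal(p$sigma_W[1], sqrt(4.8))
  expect_equal(p$sigma_W[9], 0)
  expect_true(all(diff(p$sigma_W) <= 1e-12))  # non-decreasing toward small D
})

test_that("doubling one interior window sem only widens points below it", {
  base <- data.frame(D = grid9, mean_force = 0, sem = 0.4)
  mod <- base; mod$sem[5] <- 0.8              # window at D = 17
  s0 <- propagate_uncertainty(base)
  s1 <- propagate_uncertainty(mod)
  at_or_below <- grid9 <= 17            # the window contributes to its own point
  expect_true(all(s1[at_or_below] > s0[at_or_below]))
  expect_equal(s1[!at_or_below], s0[!at_or_below])
})

test_that("missing sems are reported with their windows", {
  tab <- data.frame(D = grid9, mean_force = 0, sem = 0.4)
  tab$sem[c(2, 4)] <- NA
  expect_error(propagate_uncertainty(tab), "11, 15")
})

test_that("minimum location, tie-breaking and boundary flags", {
  W <- c(-10, -17.5, -12, -8, -5, -3, -1.5, -0.5, 0)
  m <- locate_minimum(pmf_profile(grid9, W))
  expect_equal(m$D, 11)
  expect_equal(m$W, -17.5)
  expect_false(m$boundary)
  expect_true(is.list(m$refined))

  m0 <- locate_minimum(pmf_profile(grid9, rep(0, 9)))
  expect_equal(m0$D, 9)                       # tie broken toward smaller D
  expect_equal(m0$W, 0)
  expect_true(m0$boundary)

  mono <- locate_minimum(pmf_profile(grid9, grid9 - 25))
  expect_equal(mono$D, 9)
  expect_true(mono$boundary)
})

test_that("unsorted input is sorted with a notice; duplicates are errors", {
  tab <- data.frame(D = rev(grid9), mean_force = 1, sem = 0)
  expect_message(p <- integrate_pmf(tab), "sort")
  expect_equal(p$W[1], 16)
  dup <- data.frame(D = c(9, 11, 11, 13), mean_force = 1, sem = 0)
  expect_error(integrate_pmf(dup), "duplicate")
})

test_that("non-uniform grids (plateau extension windows) integrate correctly", {
  D <- c(grid9, 27)
  p <- integrate_pmf(data.frame(D = D, mean_force = 1, sem = 0.4))
  expect_equal(p$anchor_D, 27)
  expect_equal(p$W, 27 - D)
  expect_equal(p$sigma_W[10], 0)
})

test_that("PMF TSV and JSON summary round-trip", {
  p <- integrate_pmf(data.frame(D = grid9, mean_force = rnorm(9), sem = 0.3))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_pmf(p, tsv, summary_path = js)
  p2 <- read_pmf(tsv)
  expect_equal(p2$W, p$W)
  expect_equal(p2$sigma_W, p$sigma_W)
  summ <- jsonlite::fromJSON(js)
  expect_equal(summ$anchor_D, 25)
  expect_equal(summ$minimum$W, min(p$W))
})
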