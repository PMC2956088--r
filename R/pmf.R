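#' Potential-of-mean-force profile
#'
#' Container for W(D) on a separation grid, with per-point uncertainties.
#' Profiles produced by [integrate_pmf()] are anchored so that W at the
#' largest (anchor) distance is exactly zero — they reach their zero-energy
#' plateau by construction; directly constructed profiles (e.g. analytic test
#' cases) may carry any values.
#'
#' @param D separations, Angstrom (strictly ascending, >= 2 points)
#' @param W free energy at each separation, kcal/mol
#' @param sigma_W per-point uncertainty, kcal/mol (recycled; 0 at the anchor)
#' @param anchor_D anchoring distance, Angstrom (default: the largest D)
#' @param windows optional window table the profile was integrated from
#' @return object of class `pmf_profile`
#' @export
pmf_profile <- function(D, W, sigma_W = 0, anchor_D = max(D), windows = NULL) {
  if (length(D) < 2) stop("a PMF profile needs at least two grid points")
  if (is.unsorted(D, strictly = TRUE)) stop("D must be strictly ascending")
  if (any(D <= 0)) stop("separations must be positive")
  if (length(W) != length(D)) stop("W and D lengths differ")
  sigma_W <- rep_len(sigma_W, length(D))
  if (any(sigma_W < 0)) stop("sigma_W must be non-negative")
  structure(list(D = D, W = W, sigma_W = sigma_W, anchor_D = anchor_D,
                 windows = windows),
            class = "pmf_profile")
}

.windows_df <- function(estimates) {
  if (is.data.frame(estimates)) {
    if (!all(c("D", "mean_force") %in% names(estimates)))
      stop("window table needs columns D and mean_force")
    df <- estimates
  } else {
    df <- window_table(estimates)
  }
  if (nrow(df) < 2) stop("PMF integration needs at least two windows")
  if (anyDuplicated(df$D))
    stop(sprintf("duplicate window separations: %s",
                 paste(unique(df$D[duplicated(df$D)]), collapse = ", ")))
  if (is.unsorted(df$D)) {
    message("window table not sorted by D; sorting")
    df <- df[order(df$D), ]
  }
  df
}

#' Integrate windowed mean forces into a PMF
#'
#' Thermodynamic integration of the mean force over the separation
#' coordinate: `W(D) = -integral from the anchor down to D of Fbar(D') dD'`,
#' evaluated by the composite trapezoidal rule on the window grid and anchored
#' to zero at the largest simulated separation (the profile is assumed to have
#' plateaued there). Equivalently
#' `W(D_i) = sum over intervals above D_i of h_j/2 * (Fbar_j + Fbar_j+1)`.
#' The rule is exact whenever the mean force is linear in D; per-interval
#' widths may differ (plateau-check extension windows are supported).
#'
#' Uncertainties are propagated from the per-window standard errors via
#' [propagate_uncertainty()] when the table carries a `sem` column.
#'
#' @param estimates a window table (`data.frame` with `D`, `mean_force` and
#'   optionally `sem`) or a list of [mean_force()] estimates
#' @return a [pmf_profile()]
#' @examples
#' w <- data.frame(D = seq(9, 25, 2), mean_force = 1, sem = 0)
#' integrate_pmf(w)$W[1]  # constant force 1 gives W(9) = 25 - 9 = 16
#' @export
integrate_pmf <- function(estimates) {
  df <- .windows_df(estimates)
  D <- df$D
  f <- df$mean_force
  n <- length(D)
  h <- diff(D)
  seg <- h / 2 * (f[-n] + f[-1])          # integral of Fbar over each interval
  W <- c(rev(cumsum(rev(seg))), 0)        # sum of intervals above each point
  sigma <- if ("sem" %in% names(df)) propagate_uncertainty(df) else rep(0, n)
  pmf_profile(D, W, sigma, anchor_D = D[n], windows = df)
}

#' Propagate window uncertainties onto the PMF
#'
#' Treats the window mean forces as independent estimates (each window is a
#' separate simulation) and propagates their standard errors through the
#' composite trapezoidal weights: for grid point `i`,
#' `sigma_W(i)^2 = sum_{j >= i} (w_j * sem_j)^2`, where `w_j` is window `j`'s
#' total trapezoid weight between `D_i` and the anchor (half the adjacent
#' interval widths). The uncertainty is zero at the anchor and non-decreasing
#' toward smaller separations.
#'
#' @param estimates window table with columns `D` and `sem` (and
#'   `mean_force`), or a list of [mean_force()] estimates
#' @return numeric vector `sigma_W`, kcal/mol, one value per window
#' @export
propagate_uncertainty <- function(estimates) {
  df <- if (is.data.frame(estimates) && !"mean_force" %in% names(estimates)) {
    cbind(estimates, mean_force = 0)
  } else estimates
  df <- .windows_df(df)
  if (!"sem" %in% names(df)) stop("window table lacks a sem column")
  if (any(is.na(df$sem)))
    stop(sprintf("missing sem at windows: %s",
                 paste(df$D[is.na(df$sem)], collapse = ", ")))
  D <- df$D; sem <- df$sem; n <- length(D)
  h <- diff(D)
  sigma2 <- numeric(n)
  for (i in seq_len(n - 1)) {
    j <- i:n
    w <- numeric(length(j))
    hs <- h[i:(n - 1)]                    # interval widths above D_i
    w[1] <- hs[1] / 2
    w[length(j)] <- hs[length(hs)] / 2
    if (length(j) > 2)
      w[2:(length(j) - 1)] <- (hs[-length(hs)] + hs[-1]) / 2
    sigma2[i] <- sum((w * sem[j])^2)
  }
  sqrt(sigma2)
}

#' Locate the PMF minimum
#'
#' Returns the grid point of minimal W; ties are broken toward the smaller
#' separation so output is deterministic. A minimum sitting on either grid
#' edge is flagged (`boundary = TRUE`) since the true extremum may lie outside
#' the simulated range. For interior minima a parabolic refinement through the
#' minimum and its two neighbours is reported separately.
#'
#' @param profile a [pmf_profile()]
#' @return list with `D`, `W`, `boundary`, and (for interior minima)
#'   `refined = list(D, W)` from the local parabola
#' @export
locate_minimum <- function(profile) {
  stopifnot(inherits(profile, "pmf_profile"))
  W <- profile$W; D <- profile$D
  i <- which(W == min(W))[1]              # ascending D: first hit = smallest D
  out <- list(D = D[i], W = W[i],
              boundary = i == 1L || i == length(W), refined = NULL)
  if (!out$boundary) {
    x <- D[(i - 1):(i + 1)]; y <- W[(i - 1):(i + 1)]
    fit <- lm(y ~ x + I(x^2))
    a <- coef(fit)[[3]]; b <- coef(fit)[[2]]; c0 <- coef(fit)[[1]]
    if (is.finite(a) && a > 0) {
      xs <- -b / (2 * a)
      out$refined <- list(D = xs, W = c0 + b * xs + a * xs^2)
    }
  }
  out
}

#' @export
print.pmf_profile <- function(x, ...) {
  m <- locate_minimum(x)
  cat(sprintf("PMF profile: %d points on [%g, %g] A, anchored at %g A\n",
              length(x$D), min(x$D), max(x$D), x$anchor_D))
  cat(sprintf("  minimum: W = %.3f kcal/mol at D = %g A%s\n", m$W, m$D,
              if (m$boundary) " (boundary)" else ""))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...,
                             xlab = "D (Angstrom)", ylab = "W(D) (kcal/mol)") {
  graphics::plot(x$D, x$W, type = "b", pch = 16, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  has <- x$sigma_W > 0
  if (any(has))
    graphics::arrows(x$D[has], x$W[has] - x$sigma_W[has],
                     x$D[has], x$W[has] + x$sigma_W[has],
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Write / read a PMF profile as TSV, plus a JSON summary
#'
#' The TSV carries `D`, `W` and `sigma_W` with units in a `#` header; the
#' summary records the anchor and the located minimum.
#'
#' @param profile a [pmf_profile()]
#' @param path TSV path
#' @param summary_path optional JSON summary path
#' @return `path` (writer) or a [pmf_profile()] (reader)
#' @export
write_pmf <- function(profile, path, summary_path = NULL) {
  stopifnot(inherits(profile, "pmf_profile"))
  con <- file(path, "w")
  writeLines("# columns: D_angstrom W_kcal_mol sigma_W_kcal_mol", con)
  write.table(data.frame(D = profile$D, W = profile$W, sigma_W = profile$sigma_W),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(summary_path)) {
    m <- locate_minimum(profile)
    jsonlite::write_json(list(anchor_D = profile$anchor_D,
                              minimum = list(D = m$D, W = m$W,
                                             boundary = m$boundary)),
                         summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  pmf_profile(tab$D, tab$W, tab$sigma_W)
}
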