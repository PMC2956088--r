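make_topo <- function(...) synthetic_topology(...)

test_that("frame count and times follow floor(duration/dt) + 1", {
  topo <- make_topo(n_arg = c(1, 0), n_chloride = 1)
  traj <- generate_trajectory(contact_schedule(), duration = 12, dt = 0.2,
                              topology = topo)
  expect_equal(dim(traj$coords)[1], 61)
  expect_equal(traj$times[1], 0)
  expect_equal(traj$times[61], 12)
})

test_that("with an empty schedule every partner idles at baseline distance", {
  topo <- make_topo(n_arg = c(1, 1), n_chloride = 2,
                    lipid_oxygens = c(phosphate = 1))
  sch <- contact_schedule(baseline_distance = 12)
  traj <- generate_trajectory(sch, duration = 4, dt = 0.2, topology = topo)
  gref <- which(traj$topology$role == "guanidinium_atom")
  partners <- which(traj$topology$role %in% c("chloride", "lipid_oxygen"))
  for (p in partners) {
    dmin <- rep(Inf, dim(traj$coords)[1])
    for (g in gref) dmin <- pmin(dmin, pgdimer:::.pair_dist(traj, g, p))
    # anchored exactly at baseline from the nearest arginine site
    expect_equal(unique(round(dmin, 9)), 12)
  }
  ev <- detect_ionic_bridges(traj)
  expect_equal(nrow(ev), 0)
})

test_that("scheduled pairs sit at the scheduled distance for the whole interval", {
  topo <- make_topo(n_arg = c(1, 0), n_chloride = 1)
  g <- topology_atom(topo, "guanidinium_atom", peptide_id = 1, residue_id = 1)
  cl <- topology_atom(topo, "chloride")
  sch <- contact_schedule(data.frame(partner = cl, target = g, distance = 4,
                                     start_ps = 2, end_ps = 14))
  traj <- generate_trajectory(sch, duration = 20, dt = 0.2, topology = topo)
  drow <- pgdimer:::.pair_dist(traj, match(g, topo$index), match(cl, topo$index))
  active <- traj$times >= 2 & traj$times < 14
  expect_equal(sum(active), 60)              # 12 ps at dt = 0.2
  expect_true(all(abs(drow[active] - 4) < 1e-9))
  expect_true(all(drow[!active] > 7.6))      # never a spurious contact
  # the 6 A case: inside the solvent-separated shell, outside contact range
  sch6 <- contact_schedule(data.frame(partner = cl, target = g, distance = 6,
                                      start_ps = 0, end_ps = 20))
  traj6 <- generate_trajectory(sch6, duration = 20, dt = 0.2, topology = topo)
  d6 <- pgdimer:::.pair_dist(traj6, match(g, topo$index), match(cl, topo$index))
  act6 <- traj6$times < 20
  expect_true(all(d6[act6] <= 7.6 & d6[act6] > 4.3))
})

test_that("scanning frames recovers scheduled intervals to within one frame", {
  topo <- make_topo(n_arg = c(2, 1), n_chloride = 2)
  g11 <- topology_atom(topo, "guanidinium_atom", 1, 1)
  g21 <- topology_atom(topo, "guanidinium_atom", 2, 1)
  cl1 <- topology_atom(topo, "chloride", which = 1)
  cl2 <- topology_atom(topo, "chloride", which = 2)
  sch <- contact_schedule(data.frame(
    partner = c(cl1, cl2), target = c(g11, g21),
    distance = c(4, 5.5), start_ps = c(1, 6.4), end_ps = c(13, 18.2)))
  traj <- generate_trajectory(sch, duration = 20, dt = 0.2, topology = topo)
  for (r in 1:2) {
    e <- sch$entries[r, ]
    d <- pgdimer:::.pair_dist(traj, match(e$target, topo$index),
                              match(e$partner, topo$index))
    inside <- which(d <= 7.6)
    expect_lte(abs(traj$times[min(inside)] - e$start_ps), 0.2 + 1e-9)
    expect_lte(abs(traj$times[max(inside)] - (e$end_ps - 0.2)), 0.2 + 1e-9)
  }
})

test_that("conflicting overlapping intervals for one partner are rejected", {
  topo <- make_topo(n_arg = c(1, 0), n_chloride = 1)
  g <- topology_atom(topo, "guanidinium_atom", 1, 1)
  cl <- topology_atom(topo, "chloride")
  expect_error(contact_schedule(data.frame(
    partner = cl, target = g, distance = c(4, 6),
    start_ps = c(0, 5), end_ps = c(10, 15))), "conflicting")
  # agreeing overlap is fine
  expect_silent(contact_schedule(data.frame(
    partner = cl, target = g, distance = c(4, 4),
    start_ps = c(0, 5), end_ps = c(10, 15))))
})

test_that("trajectory generation is deterministic and validated", {
  topo <- make_topo(n_arg = c(1, 0), n_chloride = 1)
  sch <- contact_schedule()
  a <- generate_trajectory(sch, 5, 0.2, topo)
  b <- generate_trajectory(sch, 5, 0.2, topo)
  expect_identical(a$coords, b$coords)
  expect_error(generate_trajectory(sch, 5, 0, topo), "dt")
  g <- topology_atom(topo, "guanidinium_atom", 1, 1)
  bad <- contact_schedule(data.frame(partner = 99, target = g, distance = 4,
                                     start_ps = 0, end_ps = 2))
  expect_error(generate_trajectory(bad, 5, 0.2, topo), "missing from the topology")
  late <- contact_schedule(data.frame(partner = topology_atom(topo, "chloride"),
                                      target = g, distance = 4,
                                      start_ps = 0, end_ps = 9))
  expect_error(generate_trajectory(late, 5, 0.2, topo), "duration")
})

test_that("extended XYZ and topology sidecar round-trip", {
  topo <- make_topo(n_arg = c(1, 1), n_chloride = 1,
                    lipid_oxygens = c(ester = 1))
  g <- topology_atom(topo, "guanidinium_atom", 1, 1)
  cl <- topology_atom(topo, "chloride")
  sch <- contact_schedule(data.frame(partner = cl, target = g, distance = 4,
                                     start_ps = 0, end_ps = 3))
  traj <- generate_trajectory(sch, 5, 0.2, topo)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  tjs <- withr::local_tempfile(fileext = ".json")
  write_xyz(traj, xyz)
  write_topology(topo, tjs)
  topo2 <- read_topology(tjs)
  traj2 <- read_xyz(xyz, topology = topo2)
  expect_equal(traj2$coords, traj$coords, tolerance = 1e-6)
  expect_equal(traj2$times, traj$times)
  expect_equal(topo2$role, topo$role)
  expect_equal(topo2$oxygen_class, topo$oxygen_class)
  expect_equal(topo2$peptide_id, topo$peptide_id)
  # the reread trajectory supports the census identically
  ev1 <- detect_ionic_bridges(traj, params = census_params(persistence_ps = 2))
  ev2 <- detect_ionic_bridges(traj2, params = census_params(persistence_ps = 2))
  expect_equal(as.data.frame(ev1), as.data.frame(ev2), tolerance = 1e-6)
})

test_that("topology selectors find atoms and report misses", {
  topo <- make_topo(n_arg = c(2, 1), n_chloride = 1)
  expect_equal(length(unique(topo$index)), nrow(topo))
  i <- topology_atom(topo, "guanidinium_atom", peptide_id = 2, residue_id = 1)
  expect_equal(topo$peptide_id[match(i, topo$index)], 2)
  expect_error(topology_atom(topo, "sodium"), "no atom")
})
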