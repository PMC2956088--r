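# Independent brute-force oracles used to cross-check the package
# implementations on small fixtures. These deliberately share no code with
# the package internals: plain loops over frames, pairs and atoms.

# Euclidean distance between two atoms in one frame of a trajectory
.odist <- function(traj, f, i, j) {
  sqrt(sum((traj$coords[f, i, ] - traj$coords[f, j, ])^2))
}

# Brute-force ionic-bridge event scan: per (arginine, partner) pair walk the
# frames one by one, track consecutive qualifying runs, apply the persistence
# rule, and tier each run by majority contact qualification.
oracle_bridge_events <- function(traj, params) {
  topo <- traj$topology
  nf <- dim(traj$coords)[1]
  gu <- which(topo$role == "guanidinium_atom")
  args <- unique(data.frame(p = topo$peptide_id[gu], r = topo$residue_id[gu]))
  partners <- which(topo$role %in% c("chloride", "lipid_oxygen"))
  out <- list()
  for (ai in seq_len(nrow(args))) {
    gset <- gu[topo$peptide_id[gu] == args$p[ai] & topo$residue_id[gu] == args$r[ai]]
    for (pi in partners) {
      run_start <- NA; csp_run <- 0; dmin_run <- Inf
      flush <- function(end_frame) {
        if (is.na(run_start)) return()
        len <- end_frame - run_start + 1
        if (len * params$frame_dt >= params$persistence_ps - 1e-9) {
          out[[length(out) + 1]] <<- data.frame(
            partner = topo$index[pi],
            partner_kind = if (topo$role[pi] == "chloride") "chloride"
                           else topo$oxygen_class[pi],
            peptide_id = args$p[ai], residue_id = args$r[ai],
            tier = if (csp_run >= len / 2) "CSP" else "SSSP",
            start_frame = run_start, end_frame = end_frame,
            n_frames = len, n_csp_frames = csp_run,
            min_distance = dmin_run, stringsAsFactors = FALSE)
        }
      }
      for (f in seq_len(nf)) {
        d <- Inf
        for (g in gset) d <- min(d, .odist(traj, f, g, pi))
        if (d <= params$sssp_cutoff) {
          if (is.na(run_start)) { run_start <- f; csp_run <- 0; dmin_run <- Inf }
          if (d <= params$csp_cutoff) csp_run <- csp_run + 1
          dmin_run <- min(dmin_run, d)
        } else {
          flush(f - 1); run_start <- NA
        }
      }
      flush(nf)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# Brute-force per-frame distinct-partner bridge counts
oracle_bridge_counts <- function(events, n_frames, topo) {
  n_cl <- numeric(n_frames); n_o <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    seen_cl <- c(); seen_o <- c()
    if (!is.null(events)) for (r in seq_len(nrow(events))) {
      if (f >= events$start_frame[r] && f <= events$end_frame[r]) {
        if (events$partner_kind[r] == "chloride")
          seen_cl <- union(seen_cl, events$partner[r])
        else seen_o <- union(seen_o, events$partner[r])
      }
    }
    n_cl[f] <- length(seen_cl); n_o[f] <- length(seen_o)
  }
  list(N_Cl = mean(n_cl), N_O = mean(n_o))
}

# Brute-force hydrogen-bond count per frame
oracle_hbond_counts <- function(traj, params) {
  topo <- traj$topology
  nf <- dim(traj$coords)[1]
  don <- which(topo$role == "hbond_donor_h")
  acc <- which(topo$role == "hbond_acceptor")
  endo <- numeric(nf); exo <- numeric(nf)
  for (f in seq_len(nf)) for (i in don) for (j in acc) {
    pd <- topo$peptide_id[i]; pa <- topo$peptide_id[j]
    d <- .odist(traj, f, i, j)
    if (d < params$hbond_cutoff) {
      if (!is.na(pd) && !is.na(pa) && pd != pa) endo[f] <- endo[f] + 1
      else if (xor(is.na(pd), is.na(pa))) exo[f] <- exo[f] + 1
    }
  }
  list(endogenic = mean(endo), exogenic = mean(exo))
}

# Stationary AR(1) series with given stationary sd (independent of the
# package generator; used to calibrate the error machinery)
oracle_ar1 <- function(n, phi, sigma, seed) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sigma)
  innov <- rnorm(n - 1, 0, sigma * sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}

# Gaussian-well test landscape, tabulated densely (smooth everywhere)
gaussian_well_landscape <- function(depth = 5, center = 13, sd = 2.5,
                                    domain = c(9, 25), h = 0.01) {
  D <- seq(domain[1], domain[2], by = h)
  landscape("tabulated",
            table = data.frame(D = D, W = -depth * exp(-(D - center)^2 / (2 * sd^2))),
            domain = domain)
}
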