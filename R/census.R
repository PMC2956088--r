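#' Interface-census parameters
#'
#' Distance and persistence criteria for the ionic-bridge and hydrogen-bond
#' census. A contact solute pair (CSP) is a direct ionic bridge: any atom of
#' an arginine guanidinium group within `csp_cutoff` of a chloride ion or an
#' anionic lipid head-group oxygen. A solvent-separated solute-peptide pair
#' (SSSP) is the water-mediated analogue within `sssp_cutoff`. An interaction
#' only counts as a bridge when it persists for at least `persistence_ps`
#' consecutive picoseconds. A hydrogen bond is a donor-hydrogen / acceptor
#' pair closer than `hbond_cutoff`.
#'
#' @param csp_cutoff contact-pair distance cutoff, Angstrom (default 4.3)
#' @param sssp_cutoff solvent-separated cutoff, Angstrom (default 7.6)
#' @param persistence_ps minimum persistent-contact duration, ps (default 10)
#' @param hbond_cutoff hydrogen-bond distance cutoff, Angstrom (default 2.4)
#' @param frame_dt frame spacing, ps (default 0.2)
#' @param gap_tolerance frames of sub-cutoff interruption bridged inside a
#'   run (default 0 = strict continuity)
#' @return object of class `census_params`
#' @export
census_params <- function(csp_cutoff = 4.3, sssp_cutoff = 7.6,
                          persistence_ps = 10, hbond_cutoff = 2.4,
                          frame_dt = 0.2, gap_tolerance = 0) {
  if (!(csp_cutoff > 0 && csp_cutoff < sssp_cutoff))
    stop(sprintf("need 0 < csp_cutoff < sssp_cutoff (got %g, %g)",
                 csp_cutoff, sssp_cutoff))
  if (persistence_ps < 0) stop("persistence_ps must be >= 0")
  if (hbond_cutoff <= 0) stop("hbond_cutoff must be positive")
  if (frame_dt <= 0) stop("frame_dt must be positive")
  if (gap_tolerance < 0 || gap_tolerance > 2)
    stop("gap_tolerance must be 0, 1 or 2 frames")
  structure(list(csp_cutoff = csp_cutoff, sssp_cutoff = sssp_cutoff,
                 persistence_ps = persistence_ps, hbond_cutoff = hbond_cutoff,
                 frame_dt = frame_dt, gap_tolerance = as.integer(gap_tolerance)),
            class = "census_params")
}

# maximal runs of TRUE in a logical vector, optionally bridging short gaps
.runs <- function(qual, gap = 0L) {
  if (gap > 0L && any(qual)) {
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values))
      if (!r$values[k] && r$lengths[k] <= gap &&
          k > 1 && k < length(r$values))
        qual[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
  }
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect persistent ionic bridges
#'
#' For every (arginine, partner) pair — partners are chloride ions and lipid
#' oxygens — the per-frame distance is the minimum over the arginine's
#' guanidinium atoms to the partner. Frames within the solvent-separated
#' cutoff qualify; maximal consecutive runs of qualifying frames whose
#' inclusive duration (`n_frames * frame_dt`) reaches the persistence
#' threshold become contact events. An event is tiered CSP when at least half
#' of its frames are within the contact cutoff, SSSP otherwise; the per-frame
#' contact counts are kept on the event so the tier choice is auditable.
#'
#' @param traj a [generate_trajectory()] / [read_xyz()] trajectory
#' @param topology topology table (defaults to the one attached to `traj`)
#' @param params a [census_params()]
#' @param arginines optional `data.frame(peptide_id, residue_id)` declaring
#'   the arginines expected to carry guanidinium atoms; declared residues
#'   without guanidinium atoms raise an error
#' @return `data.frame` of class `contact_events`: partner, partner_kind,
#'   peptide_id, residue_id, tier, start_frame, end_frame, n_frames,
#'   n_csp_frames, min_distance, duration_ps
#' @export
detect_ionic_bridges <- function(traj, topology = traj$topology,
                                 params = census_params(),
                                 arginines = NULL) {
  stopifnot(inherits(params, "census_params"))
  if (is.null(topology)) stop("no topology available for the trajectory")
  n_frames <- dim(traj$coords)[1]
  if (dim(traj$coords)[2] != nrow(topology))
    stop("topology does not cover all trajectory atoms")

  guan <- topology[topology$role == "guanidinium_atom", ]
  found <- unique(guan[, c("peptide_id", "residue_id")])
  if (is.null(arginines)) {
    arginines <- found
  } else {
    have <- paste(found$peptide_id, found$residue_id)
    want <- paste(arginines$peptide_id, arginines$residue_id)
    missing <- !want %in% have
    if (any(missing))
      stop(sprintf("arginine(s) with no guanidinium atoms in topology: %s",
                   paste(sprintf("peptide %s residue %s",
                                 arginines$peptide_id[missing],
                                 arginines$residue_id[missing]),
                         collapse = "; ")))
  }
  partners <- topology[topology$role %in% c("chloride", "lipid_oxygen"), ]

  events <- list()
  if (nrow(arginines) && nrow(partners)) {
    for (a in seq_len(nrow(arginines))) {
      gat <- which(topology$role == "guanidinium_atom" &
                     topology$peptide_id == arginines$peptide_id[a] &
                     topology$residue_id == arginines$residue_id[a])
      for (p in seq_len(nrow(partners))) {
        prow <- which(topology$index == partners$index[p])
        dmin <- rep(Inf, n_frames)
        for (g in gat) dmin <- pmin(dmin, .pair_dist(traj, g, prow))
        qual <- dmin <= params$sssp_cutoff
        if (!any(qual)) next
        runs <- .runs(qual, params$gap_tolerance)
        for (r in seq_len(nrow(runs))) {
          fr <- runs$start[r]:runs$end[r]
          dur <- length(fr) * params$frame_dt
          if (dur < params$persistence_ps - 1e-9) next
          ncsp <- sum(dmin[fr] <= params$csp_cutoff)
          events[[length(events) + 1]] <- data.frame(
            partner = partners$index[p],
            partner_kind = if (partners$role[p] == "chloride") "chloride"
                           else partners$oxygen_class[p],
            peptide_id = arginines$peptide_id[a],
            residue_id = arginines$residue_id[a],
            tier = if (ncsp >= length(fr) / 2) "CSP" else "SSSP",
            start_frame = runs$start[r], end_frame = runs$end[r],
            n_frames = length(fr), n_csp_frames = ncsp,
            min_distance = min(dmin[fr]),
            duration_ps = dur,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(partner = integer(), partner_kind = character(),
               peptide_id = integer(), residue_id = integer(),
               tier = character(), start_frame = integer(),
               end_frame = integer(), n_frames = integer(),
               n_csp_frames = integer(), min_distance = numeric(),
               duration_ps = numeric(), stringsAsFactors = FALSE)
  attr(out, "n_frames") <- n_frames
  attr(out, "frame_dt") <- params$frame_dt
  class(out) <- c("contact_events", "data.frame")
  out
}

#' Time-averaged ionic-bridge census
#'
#' Per frame, the bridge count is the number of *distinct* partners active in
#' at least one event — a chloride bridging arginines of both peptides counts
#' once (collective dimer census; `bridging_only = TRUE` instead restricts to
#' partners simultaneously in events with both peptides). `N_Cl` and `N_O`
#' are means over all frames; the oxygen-class breakdown attributes each
#' oxygen event to its class; CSP/SSSP fractions are computed over
#' partner-frames using the per-frame contact qualification stored on the
#' events.
#'
#' @param events a [detect_ionic_bridges()] result
#' @param n_frames number of trajectory frames (defaults to the attribute on
#'   `events`)
#' @param frame_dt frame spacing, ps (defaults likewise)
#' @param bridging_only count only partners concurrently bonded to both
#'   peptides
#' @return object of class `bridge_census`: `N_Cl`, `N_O`, `class_breakdown`,
#'   `csp_fraction`, `sssp_fraction`, `per_frame` counts table
#' @export
census_bridges <- function(events, n_frames = attr(events, "n_frames"),
                           frame_dt = attr(events, "frame_dt"),
                           bridging_only = FALSE) {
  if (is.null(n_frames)) stop("n_frames must be supplied")
  if (nrow(events) && max(events$end_frame) > n_frames)
    stop("events reference frames beyond n_frames")

  per_frame_cl <- numeric(n_frames)
  per_frame_o <- numeric(n_frames)
  class_frames <- c(hydroxyl = 0, phosphate = 0, ester = 0, carbonyl = 0)
  tot_pf <- 0; csp_pf <- 0

  if (nrow(events)) {
    for (p in unique(events$partner)) {
      ev <- events[events$partner == p, ]
      act <- rep(FALSE, n_frames)
      by_pep <- list()
      for (r in seq_len(nrow(ev))) {
        fr <- ev$start_frame[r]:ev$end_frame[r]
        act[fr] <- TRUE
        pid <- as.character(ev$peptide_id[r])
        if (is.null(by_pep[[pid]])) by_pep[[pid]] <- rep(FALSE, n_frames)
        by_pep[[pid]][fr] <- TRUE
      }
      if (bridging_only) {
        act <- if (length(by_pep) >= 2)
          Reduce(`&`, by_pep[as.character(1:2)]) else rep(FALSE, n_frames)
        act[is.na(act)] <- FALSE
      }
      kind <- ev$partner_kind[1]
      if (kind == "chloride") per_frame_cl <- per_frame_cl + act
      else {
        per_frame_o <- per_frame_o + act
        class_frames[kind] <- class_frames[kind] + sum(act)
      }
    }
    tot_pf <- sum(events$n_frames)
    csp_pf <- sum(events$n_csp_frames)
  }

  any_bridge <- tot_pf > 0
  ox_total <- sum(class_frames)
  structure(list(
    N_Cl = mean(per_frame_cl),
    N_O = mean(per_frame_o),
    class_breakdown = if (ox_total > 0) class_frames / ox_total else
      class_frames * NA,
    csp_fraction = if (any_bridge) csp_pf / tot_pf else NA_real_,
    sssp_fraction = if (any_bridge) 1 - csp_pf / tot_pf else NA_real_,
    per_frame = data.frame(frame = seq_len(n_frames), n_cl = per_frame_cl,
                           n_o = per_frame_o),
    n_frames = n_frames, frame_dt = frame_dt,
    bridging_only = bridging_only), class = "bridge_census")
}

#' @export
print.bridge_census <- function(x, ...) {
  cat(sprintf("bridge census over %d frames: N_Cl = %.3f, N_O = %.3f\n",
              x$n_frames, x$N_Cl, x$N_O))
  if (!is.na(x$csp_fraction))
    cat(sprintf("  CSP fraction %.2f / SSSP fraction %.2f\n",
                x$csp_fraction, x$sssp_fraction))
  invisible(x)
}

#' Hydrogen-bond census
#'
#' Per frame, a hydrogen bond exists for each donor-hydrogen / acceptor pair
#' whose distance is strictly below the cutoff. Bonds are *endogenic* when
#' the two atoms sit on different peptides of the dimer and *exogenic* when
#' exactly one atom is peptide-bound; pairs with both atoms off-peptide (or
#' on the same peptide) are ignored.
#'
#' @param traj a trajectory
#' @param topology topology table (defaults to the one attached to `traj`)
#' @param params a [census_params()]
#' @return object of class `hbond_census`: time-averaged `endogenic` and
#'   `exogenic` counts plus the `per_frame` series
#' @export
detect_hbonds <- function(traj, topology = traj$topology,
                          params = census_params()) {
  stopifnot(inherits(params, "census_params"))
  if (is.null(topology)) stop("no topology available for the trajectory")
  n_frames <- dim(traj$coords)[1]
  don <- which(topology$role == "hbond_donor_h")
  acc <- which(topology$role == "hbond_acceptor")
  endo <- numeric(n_frames); exo <- numeric(n_frames)
  for (i in don) for (j in acc) {
    pi_d <- topology$peptide_id[i]; pi_a <- topology$peptide_id[j]
    on_d <- !is.na(pi_d); on_a <- !is.na(pi_a)
    kind <- if (on_d && on_a) {
      if (pi_d != pi_a) "endo" else "skip"
    } else if (on_d || on_a) "exo" else "skip"
    if (kind == "skip") next
    bonded <- .pair_dist(traj, i, j) < params$hbond_cutoff
    if (kind == "endo") endo <- endo + bonded else exo <- exo + bonded
  }
  structure(list(endogenic = mean(endo), exogenic = mean(exo),
                 per_frame = data.frame(frame = seq_len(n_frames),
                                        endogenic = endo, exogenic = exo),
                 n_frames = n_frames),
            class = "hbond_census")
}

#' @export
print.hbond_census <- function(x, ...) {
  cat(sprintf("hydrogen bonds over %d frames: endogenic %.3f, exogenic %.3f\n",
              x$n_frames, x$endogenic, x$exogenic))
  invisible(x)
}

#' Write contact events as TSV and a census as JSON
#'
#' @param events a [detect_ionic_bridges()] result
#' @param path TSV path
#' @return `path`, invisibly
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dt <- attr(events, "frame_dt") %||% NA_real_
  df <- as.data.frame(events)
  df$start_ps <- (df$start_frame - 1) * dt
  df$end_ps <- df$end_frame * dt
  writeLines("# columns: partner partner_kind peptide_id residue_id tier start_ps end_ps min_distance_A", con)
  write.table(df[, c("partner", "partner_kind", "peptide_id", "residue_id",
                     "tier", "start_ps", "end_ps", "min_distance")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param bridges a [census_bridges()] result
#' @param hbonds a [detect_hbonds()] result (optional)
#' @export
write_census <- function(bridges, path, hbonds = NULL) {
  out <- list(N_Cl = bridges$N_Cl, N_O = bridges$N_O,
              class_breakdown = as.list(bridges$class_breakdown),
              csp_fraction = bridges$csp_fraction,
              sssp_fraction = bridges$sssp_fraction,
              n_frames = bridges$n_frames)
  if (!is.null(hbonds))
    out$hbonds <- list(endogenic = hbonds$endogenic,
                       exogenic = hbonds$exogenic)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
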