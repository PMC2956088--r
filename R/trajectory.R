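#' Synthetic role topology for census fixtures
#'
#' Builds an atom table assigning interface-census roles: arginine guanidinium
#' atoms (grouped per residue per peptide, conventional atom names NE, CZ,
#' NH1, NH2), chloride and sodium ions, anionic lipid head-group oxygens by
#' class (hydroxyl / phosphate / ester / carbonyl), and hydrogen-bond donor
#' hydrogens and acceptors either on a peptide or in the environment.
#'
#' @param n_arg number of arginines per peptide, length-2 integer vector
#' @param guanidinium_atoms atom names per guanidinium group; the first is the
#'   reference atom placed exactly at the residue site
#' @param n_chloride,n_sodium numbers of free ions
#' @param lipid_oxygens named counts per oxygen class, e.g.
#'   `c(phosphate = 2, ester = 1)`
#' @param donors,acceptors per-peptide counts of donor hydrogens / acceptors,
#'   length-2 integer vectors
#' @param n_env_donors,n_env_acceptors environment (water/lipid) donor and
#'   acceptor counts
#' @return a `data.frame` of class `topology` with 0-based `index`, `name`,
#'   `role`, `peptide_id`, `residue_id`, `oxygen_class`
#' @export
synthetic_topology <- function(n_arg = c(1, 1),
                               guanidinium_atoms = c("NE", "CZ", "NH1", "NH2"),
                               n_chloride = 1, n_sodium = 0,
                               lipid_oxygens = c(),
                               donors = c(0, 0), acceptors = c(0, 0),
                               n_env_donors = 0, n_env_acceptors = 0) {
  rows <- list()
  add <- function(name, role, peptide = NA, residue = NA, oxclass = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, role = role, peptide_id = peptide, residue_id = residue,
      oxygen_class = oxclass, stringsAsFactors = FALSE)
  }
  for (p in 1:2) {
    if (n_arg[p] > 0) for (r in seq_len(n_arg[p]))
      for (nm in guanidinium_atoms)
        add(nm, "guanidinium_atom", p, r)
    if (donors[p] > 0) for (r in seq_len(donors[p]))
      add("HD", "hbond_donor_h", p, 100 + r)
    if (acceptors[p] > 0) for (r in seq_len(acceptors[p]))
      add("OA", "hbond_acceptor", p, 200 + r)
  }
  if (n_chloride > 0) for (i in seq_len(n_chloride)) add("CL", "chloride")
  if (n_sodium > 0) for (i in seq_len(n_sodium)) add("NA", "sodium")
  if (length(lipid_oxygens)) {
    if (is.null(names(lipid_oxygens)))
      stop("lipid_oxygens must be a named count vector")
    bad <- setdiff(names(lipid_oxygens),
                   c("hydroxyl", "phosphate", "ester", "carbonyl"))
    if (length(bad)) stop("unknown oxygen class: ", paste(bad, collapse = ", "))
    for (cl in names(lipid_oxygens))
      if (lipid_oxygens[[cl]] > 0) for (i in seq_len(lipid_oxygens[[cl]]))
        add("O", "lipid_oxygen", oxclass = cl)
  }
  if (n_env_donors > 0) for (i in seq_len(n_env_donors))
    add("HW", "hbond_donor_h")
  if (n_env_acceptors > 0) for (i in seq_len(n_env_acceptors))
    add("OW", "hbond_acceptor")
  topo <- do.call(rbind, rows)
  topo <- cbind(index = seq_len(nrow(topo)) - 1L, topo)
  class(topo) <- c("topology", "data.frame")
  topo
}

#' Look up an atom index in a topology
#'
#' Convenience selector for building contact schedules: returns the 0-based
#' index of the `which`-th atom matching the given role (and, where relevant,
#' peptide and residue).
#'
#' @param topo a topology table
#' @param role atom role
#' @param peptide_id,residue_id optional filters
#' @param which ordinal among the matches
#' @return 0-based atom index
#' @export
topology_atom <- function(topo, role, peptide_id = NULL, residue_id = NULL,
                          which = 1) {
  sel <- topo$role == role
  if (!is.null(peptide_id)) sel <- sel & !is.na(topo$peptide_id) &
      topo$peptide_id == peptide_id
  if (!is.null(residue_id)) sel <- sel & !is.na(topo$residue_id) &
      topo$residue_id == residue_id
  idx <- topo$index[sel]
  if (length(idx) < which)
    stop(sprintf("no atom #%d with role '%s' in topology", which, role))
  idx[which]
}

#' Scheduled-contact plan for a synthetic trajectory
#'
#' Each entry places a mobile partner atom at an exact scalar distance from a
#' target atom (a guanidinium reference atom or a donor hydrogen) over a
#' half-open time interval `[start_ps, end_ps)`; outside its intervals the
#' partner idles at `baseline_distance` from its anchor target. Entries for
#' the same partner may not overlap in time unless they agree on target and
#' distance.
#'
#' @param entries `data.frame(partner, target, distance, start_ps, end_ps)`
#'   with 0-based atom indices; may be empty
#' @param baseline_distance idle distance, Angstrom (should exceed the
#'   solvent-separated-pair cutoff so that no unscheduled contact qualifies)
#' @return object of class `contact_schedule`
#' @export
contact_schedule <- function(entries = NULL, baseline_distance = 12) {
  if (is.null(entries))
    entries <- data.frame(partner = integer(), target = integer(),
                          distance = numeric(), start_ps = numeric(),
                          end_ps = numeric())
  need <- c("partner", "target", "distance", "start_ps", "end_ps")
  if (!all(need %in% names(entries)))
    stop("schedule entries need columns ", paste(need, collapse = ", "))
  if (any(entries$distance <= 0)) stop("scheduled distances must be positive")
  if (any(entries$end_ps <= entries$start_ps))
    stop("schedule intervals must have end_ps > start_ps")
  if (baseline_distance <= 7.6)
    warning("baseline_distance does not exceed the solvent-separated cutoff (7.6 A)")
  # overlapping intervals for the same mobile partner must agree
  if (nrow(entries) > 1) {
    for (p in unique(entries$partner)) {
      e <- entries[entries$partner == p, ]
      if (nrow(e) < 2) next
      e <- e[order(e$start_ps), ]
      for (i in seq_len(nrow(e) - 1)) {
        overlap <- e$end_ps[i] > e$start_ps[i + 1]
        if (overlap && (e$distance[i] != e$distance[i + 1] ||
                        e$target[i] != e$target[i + 1]))
          stop(sprintf(
            "conflicting overlapping intervals for partner %d (distances %g and %g)",
            p, e$distance[i], e$distance[i + 1]))
      }
    }
  }
  structure(list(entries = entries, baseline_distance = baseline_distance),
            class = "contact_schedule")
}

# Deterministic site layout: every target-capable atom group gets a slot on a
# widely spaced line (spacing >> any cutoff); guanidinium groups cluster their
# non-reference atoms perpendicular to the contact axis so the minimum
# group-partner distance is carried by the reference atom exactly.
.home_positions <- function(topo, schedule) {
  n <- nrow(topo)
  pos <- matrix(0, n, 3)
  spacing <- 500
  is_target <- topo$role %in% c("guanidinium_atom", "hbond_donor_h", "hbond_acceptor")

  # group key: guanidinium atoms cluster by (peptide, residue); others are solo
  key <- ifelse(topo$role == "guanidinium_atom",
                paste0("arg_", topo$peptide_id, "_", topo$residue_id),
                paste0("atom_", topo$index))
  target_keys <- unique(key[is_target])
  site_y <- setNames(seq_along(target_keys) * spacing, target_keys)

  # non-reference cluster atoms are offset strictly along y: partner approach
  # axes all lie in the xz-plane, so the reference atom always carries the
  # minimum group-partner distance exactly
  cluster_offsets <- rbind(c(0, 0, 0), c(0, 0.8, 0), c(0, -0.8, 0),
                           c(0, 1.6, 0), c(0, -1.6, 0), c(0, 2.4, 0))
  for (k in target_keys) {
    idx <- which(key == k & is_target)
    for (j in seq_along(idx)) {
      off <- cluster_offsets[min(j, nrow(cluster_offsets)), ]
      pos[idx[j], ] <- c(0, site_y[[k]], 0) + off
    }
  }

  # mobile/partner atoms: anchored at baseline distance from their anchor target
  partners <- which(!is_target)
  anchor_of <- function(i0) {
    e <- schedule$entries
    hit <- e$target[e$partner == i0]
    if (length(hit)) hit[1] else topo$index[is_target][1]
  }
  for (j in seq_along(partners)) {
    i <- partners[j]
    if (!any(is_target)) { pos[i, ] <- c(1000 + j * spacing, 0, 0); next }
    anchor_idx <- anchor_of(topo$index[i])
    apos <- pos[match(anchor_idx, topo$index), ]
    theta <- (j - 1) * 0.37
    pos[i, ] <- apos + schedule$baseline_distance *
      c(-cos(theta), 0, sin(theta))
  }
  pos
}

#' Generate a scheduled-contact coordinate trajectory
#'
#' Emits `floor(duration/dt) + 1` frames (times 0, dt, ..., duration). During
#' each scheduled interval the partner atom sits at exactly the scheduled
#' distance from its target atom (placed along a fixed per-partner axis on the
#' far side from the guanidinium cluster); outside its intervals it sits at
#' the schedule's baseline distance from its anchor target. All sites are
#' hundreds of Angstrom apart, so the only sub-cutoff distances are the
#' scheduled ones. The construction is deterministic.
#'
#' @param schedule a [contact_schedule()]
#' @param duration trajectory length, ps
#' @param dt frame spacing, ps
#' @param topology a [synthetic_topology()] table covering all scheduled atoms
#' @return object of class `trajectory`: list with `coords` (an
#'   `n_frames x n_atoms x 3` array), `times`, `dt` and `topology`
#' @export
generate_trajectory <- function(schedule, duration, dt, topology) {
  stopifnot(inherits(schedule, "contact_schedule"))
  if (dt <= 0) stop("dt must be positive")
  if (duration <= 0) stop("duration must be positive")
  e <- schedule$entries
  if (nrow(e) > 0) {
    if (!all(e$partner %in% topology$index) || !all(e$target %in% topology$index))
      stop("schedule references atoms missing from the topology")
    # intervals are half-open [start, end): an entry may end one frame past
    # the trajectory to cover the final frame at t = duration
    if (any(e$end_ps > duration + dt + 1e-9))
      stop("schedule intervals extend beyond the trajectory duration")
  }
  n_frames <- floor(duration / dt + 1e-9) + 1
  times <- (seq_len(n_frames) - 1) * dt
  home <- .home_positions(topology, schedule)
  n_atoms <- nrow(topology)
  coords <- array(rep(home, each = n_frames),
                  dim = c(n_frames, n_atoms, 3))

  if (nrow(e) > 0) {
    partner_seq <- which(!topology$role %in%
                           c("guanidinium_atom", "hbond_donor_h", "hbond_acceptor"))
    for (r in seq_len(nrow(e))) {
      pi_row <- match(e$partner[r], topology$index)
      ti_row <- match(e$target[r], topology$index)
      j <- match(pi_row, partner_seq)
      theta <- if (is.na(j)) 0 else (j - 1) * 0.37
      axis <- c(cos(theta), 0, sin(theta))   # +x side: opposite the cluster
      active <- times >= e$start_ps[r] - 1e-9 & times < e$end_ps[r] - 1e-9
      tp <- home[ti_row, ]
      for (d in 1:3)
        coords[active, pi_row, d] <- tp[d] + e$distance[r] * axis[d]
    }
  }
  structure(list(coords = coords, times = times, dt = dt,
                 topology = topology, schedule = schedule),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %g ps (%g ps)\n",
              dim(x$coords)[1], dim(x$coords)[2], x$dt,
              max(x$times)))
  invisible(x)
}

# distance series between two atoms (1-based row indices), over all frames
.pair_dist <- function(traj, i, j) {
  d <- traj$coords[, i, , drop = FALSE] - traj$coords[, j, , drop = FALSE]
  sqrt(rowSums(matrix(d, nrow = dim(traj$coords)[1])^2))
}

#' Write / read an extended-XYZ trajectory
#'
#' Plain-text multi-frame XYZ: per frame an atom count, a comment line
#' `frame=<i> time_ps=<t>`, then `name x y z` rows.
#'
#' @param traj a [generate_trajectory()] result
#' @param path file path
#' @param topology topology to re-attach on read (or `NULL`)
#' @return `path` (writer) or a `trajectory` (reader)
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]; na <- dim(traj$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  nm <- traj$topology$name %||% rep("X", na)
  for (f in seq_len(nf)) {
    writeLines(c(as.character(na),
                 sprintf("frame=%d time_ps=%.6f", f, traj$times[f])), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", nm,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  pos <- 1
  frames <- list()
  times <- numeric()
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1; next }
    na <- as.integer(trimws(lines[pos]))
    cmt <- lines[pos + 1]
    tm <- regmatches(cmt, regexec("time_ps=([0-9.eE+-]+)", cmt))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    block <- lines[(pos + 2):(pos + 1 + na)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    pos <- pos + 2 + na
  }
  nf <- length(frames); na <- nrow(frames[[1]])
  coords <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  dt <- if (nf > 1 && !anyNA(times)) times[2] - times[1] else 1
  structure(list(coords = coords, times = times, dt = dt,
                 topology = topology, schedule = NULL),
            class = "trajectory")
}

#' Write / read a JSON topology sidecar
#'
#' Maps each 0-based atom index to its role assignment (role, peptide_id,
#' residue_id, oxygen_class).
#'
#' @param topo a topology table
#' @param path JSON path
#' @return `path` (writer) or a topology (reader)
#' @export
write_topology <- function(topo, path) {
  jsonlite::write_json(as.data.frame(unclass(topo), stringsAsFactors = FALSE),
                       path, auto_unbox = FALSE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- jsonlite::fromJSON(path)
  for (col in c("name", "role", "oxygen_class"))
    if (!col %in% names(df)) df[[col]] <- NA
  for (col in c("peptide_id", "residue_id"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  df$index <- as.integer(df$index)
  df <- df[order(df$index), c("index", "name", "role", "peptide_id",
                              "residue_id", "oxygen_class")]
  rownames(df) <- NULL
  class(df) <- c("topology", "data.frame")
  df
}

#' Read a multi-model PDB trajectory
#'
#' Thin adapter over `bio3d::read.pdb(..., multi = TRUE)` for real
#' MODEL/ENDMDL trajectories; requires the bio3d package.
#'
#' @param path PDB file
#' @param topology topology sidecar table to attach
#' @param dt frame spacing in ps
#' @return a `trajectory`
#' @export
read_pdb_trajectory <- function(path, topology = NULL, dt = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading multi-model PDB requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  structure(list(coords = coords, times = (seq_len(nf) - 1) * dt, dt = dt,
                 topology = topology, schedule = NULL),
            class = "trajectory")
}
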