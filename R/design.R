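#' Separation-distance grid for PMF windows
#'
#' The reaction coordinate is the distance `D` between the centres of mass of
#' the two peptides. Restrained simulations are run in windows at fixed `D`
#' values on a uniform ascending grid; the default grid runs from 9 to 25
#' Angstrom in 2 Angstrom increments (nine windows), with the lower bound equal
#' to twice the effective cylinder radius of the peptide model (a = 4.5 A).
#'
#' @param dmin smallest separation (Angstrom)
#' @param dmax largest separation (Angstrom)
#' @param step grid increment (Angstrom)
#' @return numeric vector of window separations, strictly ascending
#' @examples
#' separation_grid()          # 9 11 ... 25
#' length(separation_grid())  # 9 windows
#' @export
separation_grid <- function(dmin = 9, dmax = 25, step = 2) {
  if (!is.finite(dmin) || !is.finite(dmax) || !is.finite(step))
    stop("grid bounds and step must be finite")
  if (dmin <= 0 || step <= 0)
    stop("grid bounds and step must be positive")
  if (dmax <= dmin)
    stop("dmax must exceed dmin")
  d <- seq(dmin, dmax, by = step)
  if (abs(d[length(d)] - dmax) > 1e-9)
    stop(sprintf("step %g does not divide the interval [%g, %g]", step, dmin, dmax))
  d
}

.check_grid <- function(distances) {
  if (length(distances) < 2)
    stop("a separation grid needs at least two distances")
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("all separation distances must be positive and finite")
  dd <- diff(distances)
  if (any(dd <= 0)) {
    bad <- distances[c(FALSE, dd <= 0)]
    stop(sprintf("separation grid must be strictly ascending; offending distances: %s",
                 paste(format(bad), collapse = ", ")))
  }
  if (max(dd) - min(dd) > 1e-9) {
    bad <- distances[c(FALSE, abs(dd - dd[1]) > 1e-9)]
    stop(sprintf("separation grid is not uniformly spaced; offending distances: %s",
                 paste(format(bad), collapse = ", ")))
  }
  invisible(distances)
}

#' Enumerate the window-simulation experiment design
#'
#' Builds the full factorial design of restrained window simulations:
#' every combination of dimer orientation (parallel / antiparallel beta-sheet
#' packing), environment (bulk water, membrane surface, membrane core) and
#' window separation, plus any extra per-system separations appended to verify
#' the long-distance plateau of the PMF. The default design enumerates
#' 2 x 3 x 9 = 54 systems; adding the 27 A plateau-check window for the
#' parallel/core system gives 55.
#'
#' @param grid separation grid (uniform ascending, Angstrom); see
#'   [separation_grid()]
#' @param orientations character vector of dimer packing modes
#' @param environments character vector of simulation environments
#' @param extra optional `data.frame(orientation, environment, D)` of
#'   additional separations outside the common grid
#' @param effective_radius effective cylinder radius `a` of the peptide model
#'   (Angstrom); the minimum grid distance is expected to equal `2 * a`
#' @return an object of class `experiment_design` with the enumerated
#'   `$systems` table (orientation, environment, D) and `$n_systems`
#' @examples
#' d <- build_design()
#' d$n_systems  # 54
#' @export
build_design <- function(grid = separation_grid(),
                         orientations = c("parallel", "antiparallel"),
                         environments = c("water", "surface", "core"),
                         extra = NULL,
                         effective_radius = 4.5) {
  if (length(orientations) < 1 || length(environments) < 1)
    stop("orientations and environments must be non-empty")
  .check_grid(grid)
  if (!is.finite(effective_radius) || effective_radius <= 0)
    stop("effective_radius must be positive")
  if (abs(min(grid) - 2 * effective_radius) > 1e-9)
    warning(sprintf(
      "minimum grid distance %g differs from the contact distance 2a = %g",
      min(grid), 2 * effective_radius))

  systems <- expand.grid(D = grid, environment = environments,
                         orientation = orientations,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  systems <- systems[, c("orientation", "environment", "D")]

  if (!is.null(extra)) {
    extra <- as.data.frame(extra, stringsAsFactors = FALSE)
    if (!all(c("orientation", "environment", "D") %in% names(extra)))
      stop("extra must have columns orientation, environment, D")
    if (any(!extra$orientation %in% orientations) ||
        any(!extra$environment %in% environments))
      stop("extra rows reference unknown orientation or environment")
    if (any(extra$D <= 0)) stop("extra distances must be positive")
    systems <- rbind(systems, extra[, c("orientation", "environment", "D")])
  }
  systems <- systems[order(match(systems$orientation, orientations),
                           match(systems$environment, environments),
                           systems$D), ]
  rownames(systems) <- NULL
  dup <- duplicated(systems)
  if (any(dup)) stop("duplicate (orientation, environment, D) systems in design")

  out <- list(grid = grid, orientations = orientations,
              environments = environments, extra = extra,
              effective_radius = effective_radius,
              systems = systems, n_systems = nrow(systems))
  class(out) <- "experiment_design"
  out
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Window-simulation design:", x$n_systems, "systems\n")
  cat("  orientations:", paste(x$orientations, collapse = ", "), "\n")
  cat("  environments:", paste(x$environments, collapse = ", "), "\n")
  cat(sprintf("  grid: %g..%g A in steps of %g (%d windows)\n",
              min(x$grid), max(x$grid), diff(x$grid)[1], length(x$grid)))
  if (!is.null(x$extra) && nrow(x$extra) > 0)
    cat("  extra windows:", nrow(x$extra), "\n")
  invisible(x)
}
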