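#' Ground-truth free-energy landscapes W(D)
#'
#' A landscape is the known potential of mean force used by the synthetic-data
#' generator; recovering it from simulated restraint forces validates the
#' mean-force integration. Supported forms:
#'
#' * `"flat"` — W identically zero.
#' * `"harmonic_well"` — a parabolic well of given `depth` (kcal/mol) at
#'   `center` (Angstrom). By default the parabola is untruncated and anchored to
#'   zero at the top of the domain, so the curvature is
#'   `2 * depth / (Dhi - center)^2` and the mean force is linear in `D`
#'   across the whole domain. Supplying a finite `width` (full width at
#'   W = 0) instead gives a truncated parabola that is exactly zero outside
#'   `center +/- width/2`; the mean force then jumps at the crossing points.
#'   An explicit `curvature` (kcal/mol/A^2) overrides the derived one.
#' * `"square_well"` — depth `depth` between `center - width/2` and
#'   `center + width/2`, zero outside. `edge_width > 0` replaces the hard
#'   edges by smooth tanh walls of that length scale (required for Langevin
#'   sampling, which needs a gradient everywhere).
#' * `"tabulated"` — natural cubic-spline interpolant of a user table
#'   `data.frame(D, W)`.
#'
#' All forms are anchored so that `W(Dhi) = 0` at the upper domain edge.
#'
#' @param form landscape family, see above
#' @param depth well depth, kcal/mol (non-negative)
#' @param center well centre D0, Angstrom
#' @param width full width of the well, Angstrom (`harmonic_well`: width at
#'   W = 0; `square_well`: width of the flat bottom)
#' @param curvature explicit harmonic curvature, kcal/mol/A^2
#' @param edge_width tanh edge length scale for `square_well`, Angstrom
#'   (0 = hard edges)
#' @param table `data.frame(D, W)` for `form = "tabulated"`
#' @param domain `c(Dlo, Dhi)` in Angstrom; defaults to the 9..25 window span,
#'   or the table range for tabulated landscapes
#' @return an object of class `landscape`
#' @seealso [landscape_energy()], [true_mean_force()]
#' @examples
#' ls <- landscape("harmonic_well", depth = 5, center = 13)
#' landscape_energy(ls, c(13, 25))
#' @export
landscape <- function(form = c("flat", "harmonic_well", "square_well", "tabulated"),
                      depth = 0, center = NULL, width = NULL, curvature = NULL,
                      edge_width = 0, table = NULL, domain = NULL) {
  form <- match.arg(form)
  if (!is.finite(depth) || depth < 0) stop("depth must be non-negative")

  if (form == "tabulated") {
    if (is.null(table) || !all(c("D", "W") %in% names(table)))
      stop("tabulated landscape needs table = data.frame(D, W)")
    table <- as.data.frame(table)      # configs may supply a plain list
    table <- table[order(table$D), ]
    if (anyDuplicated(table$D)) stop("tabulated landscape has duplicate D values")
    if (any(!is.finite(table$W))) stop("tabulated W values must be finite")
    domain <- domain %||% range(table$D)
  } else {
    domain <- domain %||% c(9, 25)
  }
  if (length(domain) != 2 || !all(is.finite(domain)) || domain[1] >= domain[2])
    stop("domain must be c(Dlo, Dhi) with Dlo < Dhi")

  obj <- list(form = form, depth = depth, center = center, width = width,
              curvature = curvature, edge_width = edge_width,
              table = table, domain = domain, offset = 0)

  if (form == "harmonic_well") {
    if (is.null(center)) stop("harmonic_well needs a center")
    if (center <= domain[1] || center >= domain[2])
      stop("harmonic_well center must lie inside the domain")
    if (is.null(curvature)) {
      half <- if (is.null(width)) domain[2] - center else width / 2
      if (half <= 0) stop("width must be positive")
      if (depth <= 0) stop("harmonic_well needs depth > 0 (or an explicit curvature)")
      obj$curvature <- 2 * depth / half^2
    }
    obj$half_width <- if (is.null(width)) Inf else width / 2
  } else if (form == "square_well") {
    if (is.null(center) || is.null(width)) stop("square_well needs center and width")
    if (width <= 0) stop("width must be positive")
    if (edge_width < 0) stop("edge_width must be non-negative")
    obj$edges <- c(center - width / 2, center + width / 2)
  } else if (form == "tabulated") {
    obj$spline <- splinefun(table$D, table$W, method = "natural")
  }

  class(obj) <- "landscape"
  # anchor: W(Dhi) = 0
  obj$offset <- .landscape_raw(obj, domain[2])
  obj
}

# un-anchored energy
.landscape_raw <- function(ls, D) {
  switch(ls$form,
    flat = rep(0, length(D)),
    harmonic_well = {
      x <- D - ls$center
      w <- 0.5 * ls$curvature * x^2 - ls$depth
      if (is.finite(ls$half_width)) w[abs(x) >= ls$half_width] <- 0
      w
    },
    square_well = {
      a <- ls$edges[1]; b <- ls$edges[2]; s <- ls$edge_width
      if (s == 0) {
        ifelse(D >= a & D <= b, -ls$depth, 0)
      } else {
        -ls$depth / 4 * (1 + tanh((D - a) / s)) * (1 + tanh((b - D) / s))
      }
    },
    tabulated = ls$spline(D)
  )
}

.check_domain <- function(ls, D) {
  eps <- 1e-9
  if (any(D < ls$domain[1] - eps | D > ls$domain[2] + eps))
    stop(sprintf("D outside landscape domain [%g, %g]", ls$domain[1], ls$domain[2]))
}

#' Evaluate the landscape free energy
#'
#' @param ls a [landscape()]
#' @param D separations (Angstrom), inside the domain
#' @return W(D) in kcal/mol, anchored so that W at the upper domain edge is 0
#' @export
landscape_energy <- function(ls, D) {
  stopifnot(inherits(ls, "landscape"))
  .check_domain(ls, D)
  .landscape_raw(ls, D) - ls$offset
}

#' True mean force of a landscape
#'
#' Returns `-dW/dD`, the mean force whose integral (with the thermodynamic-
#' integration sign convention) reproduces the landscape. Closed forms are used
#' where available; tabulated landscapes are differentiated by central finite
#' differences of the spline interpolant. Hard-edged square wells are only
#' differentiable away from their edges.
#'
#' @param ls a [landscape()]
#' @param D separations (Angstrom), inside the domain
#' @param h finite-difference half-step for tabulated landscapes (Angstrom)
#' @return mean force in kcal/mol/A
#' @export
true_mean_force <- function(ls, D, h = 1e-4) {
  stopifnot(inherits(ls, "landscape"))
  .check_domain(ls, D)
  switch(ls$form,
    flat = rep(0, length(D)),
    harmonic_well = {
      x <- D - ls$center
      f <- -ls$curvature * x
      if (is.finite(ls$half_width)) f[abs(x) > ls$half_width] <- 0
      f
    },
    square_well = {
      a <- ls$edges[1]; b <- ls$edges[2]; s <- ls$edge_width
      if (s == 0) {
        if (any(abs(D - a) < 1e-8 | abs(D - b) < 1e-8))
          stop("square well is not differentiable at its edges")
        rep(0, length(D))
      } else {
        # -dW/dD of the tanh-walled well
        ta <- tanh((D - a) / s); tb <- tanh((b - D) / s)
        dW <- -ls$depth / 4 * ((1 - ta^2) / s * (1 + tb) -
                               (1 + ta) * (1 - tb^2) / s)
        -dW
      }
    },
    tabulated = {
      lo <- pmax(D - h, ls$domain[1]); hi <- pmin(D + h, ls$domain[2])
      -(ls$spline(hi) - ls$spline(lo)) / (hi - lo)
    }
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape <%s> on [%g, %g] A", x$form, x$domain[1], x$domain[2]))
  if (x$form != "flat") cat(sprintf(", depth %g kcal/mol", x$depth))
  if (!is.null(x$center)) cat(sprintf(", center %g A", x$center))
  cat("\n")
  invisible(x)
}
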