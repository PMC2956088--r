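#' Fluctuation model for synthetic restraint-force series
#'
#' Describes how instantaneous restraint forces fluctuate around their mean in
#' a window simulation. Three generators are available:
#'
#' * `"iid_gaussian"` — white Gaussian noise of standard deviation `sigma`
#'   added to the true restraint force.
#' * `"ar1"` — a stationary first-order autoregressive process with lag-one
#'   coefficient `phi` and *stationary* standard deviation `sigma` (the
#'   innovation standard deviation is `sigma * sqrt(1 - phi^2)`), emulating the
#'   correlated solvent-force fluctuations of a real run, whose correlation
#'   time is `-dt / log(phi)`.
#' * `"langevin"` — overdamped Brownian dynamics of the separation coordinate
#'   on the landscape plus a harmonic restraint of stiffness `restraint_k`
#'   centred at the window separation; the recorded series is the
#'   instantaneous spring force. This is the physically faithful generator:
#'   fluctuation magnitude and correlation time emerge from `restraint_k`,
#'   `diffusion` and the temperature rather than being prescribed.
#'
#' @param model one of `"iid_gaussian"`, `"ar1"`, `"langevin"`
#' @param sigma noise standard deviation, kcal/mol/A (iid and ar1 models)
#' @param phi AR(1) lag-one coefficient, in (-1, 1)
#' @param dt sampling interval, ps (default 0.2 ps, the production-run force
#'   sampling interval)
#' @param restraint_k harmonic restraint stiffness, (kcal/mol)/A^2
#'   (default 20, the production-run value)
#' @param n_samples number of recorded samples (>= 2)
#' @param seed integer seed; `NULL` leaves the RNG state untouched
#' @param diffusion diffusion coefficient of the Langevin coordinate, A^2/ps
#' @param n_substeps Euler-Maruyama substeps per recorded sample
#' @param burn_in_ps Langevin equilibration time discarded before recording, ps
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(model = c("iid_gaussian", "ar1", "langevin"),
                       sigma = 1, phi = 0, dt = 0.2, restraint_k = 20,
                       n_samples = 5000, seed = NULL,
                       diffusion = 0.05, n_substeps = 10, burn_in_ps = 10) {
  model <- match.arg(model)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.finite(phi) || abs(phi) >= 1) stop("phi must lie in (-1, 1)")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!is.finite(n_samples) || n_samples < 2) stop("n_samples must be >= 2")
  if (model == "langevin") {
    if (!is.finite(restraint_k) || restraint_k <= 0)
      stop("restraint_k must be positive for the langevin model")
    if (!is.finite(diffusion) || diffusion <= 0)
      stop("diffusion must be positive")
    if (n_substeps < 1) stop("n_substeps must be >= 1")
  }
  structure(list(model = model, sigma = sigma, phi = phi, dt = dt,
                 restraint_k = restraint_k, n_samples = as.integer(n_samples),
                 seed = seed, diffusion = diffusion,
                 n_substeps = as.integer(n_substeps),
                 burn_in_ps = burn_in_ps),
            class = "noise_spec")
}
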