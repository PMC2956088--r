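#' Generate a synthetic restraint-force series for one window
#'
#' Emulates the production-run force record of a restrained window simulation
#' at separation `D` on a known landscape. The emitted series carries the
#' restraint sign convention: its expectation is `-Fbar(D) = +dW/dD`, the
#' force exerted *on* the restraint springs, so that negating its time average
#' (as [mean_force()] does) recovers the true mean force `Fbar = -dW/dD`.
#'
#' For the `iid_gaussian` and `ar1` models the series is
#' `dW/dD + noise`; for the `langevin` model the separation coordinate is
#' propagated by overdamped Euler-Maruyama dynamics on
#' `W(x) + restraint_k/2 * (x - D)^2` and the recorded value is the
#' instantaneous spring force `restraint_k * (D - x)`, whose stationary mean
#' equals `dW/dD` up to the stiff-spring approximation.
#'
#' @param landscape a [landscape()] providing the ground truth W(D)
#' @param noise a [noise_spec()]
#' @param D window separation, Angstrom (inside the landscape domain)
#' @param temperature temperature in K (Langevin model only)
#' @return a [force_series()]; reproducible for a given `noise$seed`
#' @export
generate_force_series <- function(landscape, noise, D, temperature = 310) {
  stopifnot(inherits(landscape, "landscape"), inherits(noise, "noise_spec"))
  .check_domain(landscape, D)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  n <- noise$n_samples

  values <- switch(noise$model,
    iid_gaussian = {
      base <- -true_mean_force(landscape, D)
      base + rnorm(n, 0, noise$sigma)
    },
    ar1 = {
      base <- -true_mean_force(landscape, D)
      innov_sd <- noise$sigma * sqrt(1 - noise$phi^2)
      x0 <- rnorm(1, 0, noise$sigma)
      x <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), noise$phi,
                                    method = "recursive", init = x0))
      base + x
    },
    langevin = .sim_langevin(landscape, noise, D, temperature)
  )

  force_series(values, dt = noise$dt, D = D,
               meta = list(seed = noise$seed,
                           spec = sprintf("%s landscape, %s noise, T=%g K",
                                          landscape$form, noise$model, temperature)))
}

# Overdamped Langevin sampling of the restrained separation coordinate.
# The inner integration loop lives in C++ (src/langevin.cpp); the landscape
# gradient is passed either as a closed form or as a dense linear-interpolation
# table for tabulated landscapes.
.sim_langevin <- function(landscape, noise, D, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  beta <- 1 / (.kB * temperature)
  form_code <- switch(landscape$form,
    flat = 0L, harmonic_well = 1L, square_well = 2L, tabulated = 3L)
  pars <- numeric(0); tabD <- numeric(0); tabF <- numeric(0)
  if (landscape$form == "harmonic_well") {
    pars <- c(landscape$curvature, landscape$center, landscape$half_width)
  } else if (landscape$form == "square_well") {
    if (landscape$edge_width <= 0)
      stop("langevin sampling of a square well needs edge_width > 0 (a gradient must exist everywhere)")
    pars <- c(landscape$depth, landscape$edges[1], landscape$edges[2],
              landscape$edge_width)
  } else if (landscape$form == "tabulated") {
    tabD <- seq(landscape$domain[1], landscape$domain[2], length.out = 2001)
    tabF <- true_mean_force(landscape, tabD)
  }
  n_burn <- as.integer(ceiling(noise$burn_in_ps / noise$dt))
  x <- cpp_langevin_positions(
    n_samples = noise$n_samples, dt = noise$dt, n_substeps = noise$n_substeps,
    x0 = D, n_burn = n_burn, restraint_center = D,
    restraint_k = noise$restraint_k, diffusion = noise$diffusion, beta = beta,
    form = form_code, pars = pars,
    dom_lo = landscape$domain[1] - 2, dom_hi = landscape$domain[2] + 2,
    tabD = tabD, tabF = tabF)
  noise$restraint_k * (D - x)
}
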