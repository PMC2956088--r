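#' Exponential autocorrelation time of a force series
#'
#' Estimates the correlation time of the restraint-force fluctuations by a
#' log-linear fit to the normalized autocorrelation function (biased 1/n
#' normalization, as returned by [stats::acf()]) over lags up to its first
#' zero crossing. To keep the fit in the well-resolved exponential regime the
#' lag range is additionally truncated where the autocorrelation falls below
#' `min_rho` (default `1/e`, i.e. the fit spans about one correlation time);
#' an unweighted log fit over the noise-dominated tail would otherwise be
#' badly biased. A constant series has no fluctuations: the function returns 0
#' with a warning and attribute `degenerate = TRUE`.
#'
#' @param series a [force_series()] (length >= 100 recommended)
#' @param max_lag largest lag considered (samples)
#' @param min_rho smallest autocorrelation retained in the fit
#' @return correlation time in ps
#' @examples
#' fs <- force_series(rnorm(1000), dt = 0.2, D = 11)
#' autocorr_time(fs) < 0.2  # white noise: no persistence
#' @export
autocorr_time <- function(series, max_lag = 2000, min_rho = exp(-1)) {
  stopifnot(inherits(series, "force_series"))
  v <- series$values
  n <- length(v)
  if (var(v) <= 0) {
    warning("constant series: autocorrelation time undefined, returning 0")
    return(structure(0, degenerate = TRUE))
  }
  # grow the lag window geometrically until the first zero crossing is seen
  lag_max <- min(n - 1, 64)
  repeat {
    rho <- as.numeric(acf(v, lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)[-1]
    if (any(rho <= 0) || lag_max >= min(n - 1, max_lag)) break
    lag_max <- min(lag_max * 4, n - 1, max_lag)
  }
  if (rho[1] <= 0) return(0)
  zero <- which(rho <= 0)[1]
  K <- if (is.na(zero)) length(rho) else zero - 1
  ks <- seq_len(K)
  keep <- rho[ks] >= min_rho
  if (any(!keep)) ks <- ks[seq_len(which(!keep)[1] - 1)]
  if (length(ks) <= 1) return(-series$dt / log(rho[1]))
  fit <- lm(log(rho[ks]) ~ ks)
  slope <- coef(fit)[[2]]
  if (slope >= 0) return(-series$dt / log(rho[1]))
  -series$dt / slope
}

#' Block-averaging standard error of the mean
#'
#' Standard error of the window mean force for a correlated series: the series
#' is cut into contiguous blocks, and the standard deviation of the block
#' means over the square root of the number of blocks estimates the error.
#' With `block_size = "auto"` the block size is doubled until the estimate
#' changes by less than 5\% between successive sizes (plateau detection),
#' subject to a floor of five correlation times per block and at least four
#' blocks.
#'
#' @param series a [force_series()]
#' @param block_size block length in samples, or `"auto"`
#' @param tau correlation time in ps (estimated via [autocorr_time()] when
#'   `NULL`; only used by auto mode for the block-length floor)
#' @return list with `sem`, `block_size`, `n_blocks`
#' @export
block_sem <- function(series, block_size = "auto", tau = NULL) {
  stopifnot(inherits(series, "force_series"))
  v <- series$values
  n <- length(v)

  one <- function(bs) {
    nb <- floor(n / bs)
    bm <- colMeans(matrix(v[seq_len(nb * bs)], nrow = bs))
    list(sem = sd(bm) / sqrt(nb), block_size = bs, n_blocks = nb)
  }

  if (is.numeric(block_size)) {
    bs <- as.integer(block_size)
    if (bs < 1) stop("block_size must be >= 1")
    if (n < 2 * bs)
      stop(sprintf("block_size %d exceeds the maximum admissible size %d for %d samples",
                   bs, floor(n / 2), n))
    return(one(bs))
  }
  if (!identical(block_size, "auto")) stop("block_size must be numeric or \"auto\"")

  if (is.null(tau)) tau <- suppressWarnings(autocorr_time(series))
  floor_bs <- max(1, ceiling(5 * tau / series$dt))
  bs <- 1
  prev <- NULL
  res <- one(bs)
  repeat {
    nxt_bs <- bs * 2
    if (floor(n / nxt_bs) < 4) break
    nxt <- one(nxt_bs)
    plateau <- bs >= floor_bs &&
      (res$sem == 0 || abs(nxt$sem - res$sem) / max(res$sem, .Machine$double.eps) < 0.05)
    prev <- res; res <- nxt; bs <- nxt_bs
    if (plateau) { res <- prev; break }
  }
  if (res$block_size < floor_bs && floor(n / floor_bs) >= 2) {
    # doubling exhausted below the correlation-time floor: force the floor
    res <- one(min(floor_bs, floor(n / 2)))
  }
  res
}

#' Window mean force with decorrelation-aware uncertainty
#'
#' The mean force at separation `D` is minus the time average of the recorded
#' restraint forces, `Fbar(D) = -mean(F_res)`. The standard error comes from
#' block averaging ([block_sem()]) and the correlation time from
#' [autocorr_time()]; `n_effective = n / (1 + 2 tau / dt)` is the equivalent
#' number of independent samples. An optional initial burn-in fraction is
#' discarded first.
#'
#' @param series a [force_series()]
#' @param block_size passed to [block_sem()]
#' @param burn_in fraction of initial samples to discard, in `[0, 1)`
#' @return an object of class `mean_force_estimate` with fields `D`,
#'   `mean_force`, `sem`, `tau`, `block_size`, `n_effective`, `n_samples`
#' @export
mean_force <- function(series, block_size = "auto", burn_in = 0) {
  stopifnot(inherits(series, "force_series"))
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)")
  v <- series$values
  if (burn_in > 0) {
    drop <- floor(length(v) * burn_in)
    v <- v[(drop + 1):length(v)]
  }
  if (length(v) < 2)
    stop("insufficient data: a mean-force estimate needs at least two samples")
  ser <- force_series(v, dt = series$dt, D = series$D, meta = series$meta)
  tau <- suppressWarnings(autocorr_time(ser))
  bs <- block_sem(ser, block_size = block_size, tau = tau)
  est <- list(D = series$D,
              mean_force = -mean(v),
              sem = bs$sem,
              tau = as.numeric(tau),
              block_size = bs$block_size,
              n_effective = length(v) / (1 + 2 * tau / series$dt),
              n_samples = length(v))
  class(est) <- "mean_force_estimate"
  est
}

#' @export
print.mean_force_estimate <- function(x, ...) {
  cat(sprintf(
    "mean force at D = %g A: %.4f +/- %.4f kcal/mol/A (tau %.3g ps, blocks of %d, n %d)\n",
    x$D, x$mean_force, x$sem, x$tau, x$block_size, x$n_samples))
  invisible(x)
}

#' Collect mean-force estimates into a window table
#'
#' @param estimates list of [mean_force()] results
#' @return `data.frame` with one row per window: D, mean_force, sem, tau,
#'   block_size, n_samples
#' @export
window_table <- function(estimates) {
  if (inherits(estimates, "mean_force_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e)
    data.frame(D = e$D, mean_force = e$mean_force, sem = e$sem, tau = e$tau,
               block_size = e$block_size, n_samples = e$n_samples)))
}

#' Write / read a per-window mean-force table
#'
#' Tab-separated with a `#` header carrying the units.
#' @param tab data.frame from [window_table()]
#' @param path file path
#' @return `path` (writer) or the table (reader)
#' @export
write_mean_forces <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: D angstrom; mean_force, sem kcal/mol/A; ",
                    "tau ps; block_size samples"), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mean_forces
#' @export
read_mean_forces <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
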