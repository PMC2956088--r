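#' Restraint-force time series for one separation window
#'
#' Holds the instantaneous forces exerted on the harmonic restraint springs of
#' one window simulation, sampled at a fixed interval. The window mean force
#' is minus the time average of these values (see [mean_force()]).
#'
#' @param values restraint forces, kcal/mol/A (length >= 2, all finite)
#' @param dt sampling interval, ps
#' @param D window separation, Angstrom
#' @param meta optional provenance list (seed, generator spec, ...)
#' @return an object of class `force_series`
#' @export
force_series <- function(values, dt, D, meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a force series needs at least two samples")
  if (any(!is.finite(values))) stop("force series values must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!is.finite(D) || D <= 0) stop("D must be positive")
  structure(list(values = values, dt = dt, D = D, meta = meta),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf("force_series: D = %g A, %d samples at dt = %g ps (%g ps total)\n",
              x$D, length(x$values), x$dt, length(x$values) * x$dt))
  invisible(x)
}

#' @export
length.force_series <- function(x) length(x$values)

#' Write a force series as two-column text
#'
#' Format: `#`-prefixed header lines carrying the window separation, sampling
#' interval and provenance, then whitespace-delimited `time_ps  force` rows.
#'
#' @param fs a [force_series()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_force_series <- function(fs, path) {
  stopifnot(inherits(fs, "force_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# D_angstrom: %.10g", fs$D),
    sprintf("# dt_ps: %.10g", fs$dt),
    if (!is.null(fs$meta$seed)) sprintf("# seed: %d", as.integer(fs$meta$seed)),
    if (!is.null(fs$meta$spec)) sprintf("# spec: %s", fs$meta$spec),
    "# columns: time_ps force_kcal_mol_A"), con)
  t <- (seq_along(fs$values) - 1) * fs$dt
  writeLines(sprintf("%.6f %.10g", t, fs$values), con)
  invisible(path)
}

#' Read a force series written by [write_force_series()]
#'
#' @param path input file
#' @return a [force_series()]
#' @export
read_force_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(paste0("^# ", key, ":\\s*"), "", m[1])
  }
  D <- as.numeric(get("D_angstrom") %||% NA)
  dt <- as.numeric(get("dt_ps") %||% NA)
  if (is.na(D) || is.na(dt))
    stop("force series file lacks D_angstrom / dt_ps header lines")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  vals <- as.numeric(parts[, 2])
  meta <- list()
  if (!is.null(get("seed"))) meta$seed <- as.integer(get("seed"))
  if (!is.null(get("spec"))) meta$spec <- get("spec")
  force_series(vals, dt = dt, D = D, meta = meta)
}
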