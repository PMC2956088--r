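#' Default run configuration
#'
#' All defaults mirror the production protocol of the dimerization study:
#' separation grid 9..25 A in 2 A steps, force sampling every 0.2 ps,
#' restraint stiffness 20 (kcal/mol)/A^2, temperature 310 K, bound interval
#' [9, 25] A, census cutoffs 4.3 / 7.6 / 2.4 A and 10 ps persistence.
#'
#' @return a named list of class `run_config`
#' @export
default_config <- function() {
  structure(list(
    grid = list(min = 9, max = 25, step = 2),
    orientations = c("parallel", "antiparallel"),
    environments = c("water", "surface", "core"),
    extra_distances = list(),     # e.g. list(list(orientation=, environment=, D=))
    effective_radius = 4.5,
    temperature = 310,
    dmin = 9,
    dmax = 25,
    dt = 0.2,
    restraint_k = 20,
    landscape = list(form = "flat", depth = 0, center = 13),
    noise = list(model = "langevin", sigma = 1, phi = 0, n_samples = 5000,
                 diffusion = 0.05, n_substeps = 10, burn_in_ps = 10),
    census = list(csp_cutoff = 4.3, sssp_cutoff = 7.6, persistence_ps = 10,
                  hbond_cutoff = 2.4),
    quadrature_points = 401,
    n_boot = 0,
    seed = 1,
    log_level = "info",
    paths = list(output_dir = NULL)
  ), class = "run_config")
}

.validate_config <- function(cfg) {
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ls_keys <- c("form", "depth", "center", "width", "curvature", "edge_width",
               "table", "domain")
  for (sub in c("grid", "landscape", "noise", "census", "paths")) {
    if (is.null(cfg[[sub]])) next
    if (sub == "landscape") {
      # either one spec, or a list of specs keyed "<orientation>.<environment>"
      specs <- if ("form" %in% names(cfg[[sub]])) list(cfg[[sub]]) else cfg[[sub]]
      for (spec in specs) {
        bad <- setdiff(names(spec), ls_keys)
        if (length(bad))
          stop("unknown config key(s) under landscape: ",
               paste(bad, collapse = ", "))
      }
      next
    }
    bad <- setdiff(names(cfg[[sub]]), names(defaults[[sub]]))
    if (sub == "noise") bad <- setdiff(bad, "seed")
    if (length(bad))
      stop(sprintf("unknown config key(s) under %s: %s", sub,
                   paste(bad, collapse = ", ")))
  }
  merged <- modifyList(unclass(defaults), cfg)
  if (!is.null(cfg$landscape) && !"form" %in% names(cfg$landscape))
    merged$landscape <- cfg$landscape      # keyed per-system list: no merging
  with(merged, {
    if (census$csp_cutoff >= census$sssp_cutoff)
      stop(sprintf("csp_cutoff (%g) must be smaller than sssp_cutoff (%g)",
                   census$csp_cutoff, census$sssp_cutoff))
    if (temperature <= 0) stop("temperature must be positive")
    if (dmin >= dmax) stop("dmin must be smaller than dmax")
    if (dt <= 0) stop("dt must be positive")
    if (restraint_k <= 0) stop("restraint_k must be positive")
    if (!is.null(seed) && abs(seed) >= 2^31 - 10^6)
      stop("seed too large: per-system seeds must stay below 2^31")
  })
  # grid validity
  do.call(separation_grid, merged$grid[c("min", "max", "step")] |>
            setNames(c("dmin", "dmax", "step")))
  class(merged) <- "run_config"
  merged
}

#' Load and validate a run configuration
#'
#' Reads YAML (`.yaml`/`.yml`) or JSON (`.json`), rejects unknown keys with a
#' descriptive error, applies the study defaults for anything unspecified,
#' and validates cross-field constraints (cutoff ordering, positive
#' temperature and step sizes, grid uniformity). An empty file yields the
#' full default configuration. The effective configuration is echoed via
#' `message()` unless `quiet = TRUE`.
#'
#' @param path config file path
#' @param quiet suppress the effective-config echo
#' @return a validated `run_config`
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be .yaml, .yml or .json"))
  if (is.null(raw)) raw <- list()
  # yaml scalars arrive fine; ensure character vectors for the factor levels
  for (k in c("orientations", "environments"))
    if (!is.null(raw[[k]])) raw[[k]] <- as.character(unlist(raw[[k]]))
  cfg <- .validate_config(raw)
  if (!quiet) {
    message(sprintf(
      "effective config: grid %g..%g/%g A, T = %g K, D in [%g, %g], dt = %g ps, seed %s",
      cfg$grid$min, cfg$grid$max, cfg$grid$step, cfg$temperature,
      cfg$dmin, cfg$dmax, cfg$dt, format(cfg$seed)))
    message(sprintf(
      "  census cutoffs: CSP %g A, SSSP %g A, H-bond %g A, persistence %g ps",
      cfg$census$csp_cutoff, cfg$census$sssp_cutoff,
      cfg$census$hbond_cutoff, cfg$census$persistence_ps))
  }
  cfg
}

#' Save a run configuration
#'
#' Writes YAML or JSON depending on the file extension; `load_config()` on
#' the result round-trips to an identical configuration.
#'
#' @param config a `run_config`
#' @param path output path (.yaml, .yml or .json)
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- unclass(config)
  switch(ext,
    yaml = , yml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                                null = "null"),
    stop("config must be .yaml, .yml or .json"))
  invisible(path)
}

# md5 of the effective configuration, for provenance records
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}
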