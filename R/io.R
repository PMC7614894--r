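#' Read a run configuration
#'
#' Reads a YAML configuration with blocks `geometry`, `params` *or* `preset`,
#' `experiment`, `inference`, `seed` and `output_dir`, applies defaults and
#' rejects unknown keys. Times may be given in days (bare numbers) or weeks
#' (strings with a `"w"` suffix, e.g. `"8w"`), converted to days on read.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list with a resolved [crypt_geometry()] and
#'   [kinetic_params()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), class = "cryptdrift_config_error")
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw))
    abort("config file is empty", class = "cryptdrift_config_error")
  known <- c("geometry", "params", "preset", "experiment", "inference", "seed", "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
          class = "cryptdrift_config_error")
  if (!is.null(raw$params) && !is.null(raw$preset))
    abort("give exactly one of `params` or `preset`", class = "cryptdrift_config_error")
  if (is.null(raw$params) && is.null(raw$preset))
    abort("one of `params` or `preset` is required", class = "cryptdrift_config_error")

  geometry <- do.call(crypt_geometry, as_geometry_args(raw$geometry))
  params <- if (!is.null(raw$preset)) {
    if (!raw$preset %in% c("SI", "LI", "SI_LGK974"))
      abort(sprintf("unknown preset: %s", raw$preset), class = "cryptdrift_config_error")
    crypt_preset(raw$preset)
  } else {
    pk <- raw$params
    bad <- setdiff(names(pk), c("k_d", "k_r", "ratio"))
    if (length(bad))
      abort(sprintf("unknown params key(s): %s", paste(bad, collapse = ", ")),
            class = "cryptdrift_config_error")
    do.call(kinetic_params, pk)
  }
  experiment <- raw$experiment %||% list()
  if (!is.null(experiment$record_times))
    experiment$record_times <- vapply(experiment$record_times, parse_time_days, numeric(1))
  structure(list(geometry = geometry, params = params,
                 experiment = experiment,
                 inference = raw$inference %||% list(n_boot = 1000),
                 seed = raw$seed, output_dir = raw$output_dir %||% "."),
            class = "run_config")
}

as_geometry_args <- function(gl) {
  if (is.null(gl)) return(list())
  bad <- setdiff(names(gl), c("n_rows", "cells_per_row", "lgr5_rows", "centre_rows", "border_rows"))
  if (length(bad))
    abort(sprintf("unknown geometry key(s): %s", paste(bad, collapse = ", ")),
          class = "cryptdrift_config_error")
  lapply(gl, unlist)
}

# "8w" -> 56 days; bare numbers are days
parse_time_days <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  if (grepl("^[0-9.]+w$", x)) return(7 * as.numeric(sub("w$", "", x)))
  if (grepl("^[0-9.]+d?$", x)) return(as.numeric(sub("d$", "", x)))
  abort(sprintf("cannot parse time '%s' (use days or e.g. '8w')", x),
        class = "cryptdrift_config_error")
}

#' Write / read observation tables
#'
#' Delimited-text I/O for clone observation tables (and other tibbles from
#' this package). Files are comma-separated with a header row, preceded by
#' provenance comment lines (`# key: value`) recording the package version,
#' seed and any extra metadata supplied.
#'
#' @param x A tibble; list-columns (e.g. `cells_by_row`) are dropped.
#' @param path Output file.
#' @param seed Seed to record in the header.
#' @param meta Named list of extra provenance fields.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path, seed = NULL, meta = list()) {
  x <- select(as_tibble(x), -dplyr::where(is.list))
  hdr <- c(sprintf("# generator: cryptdrift %s", as.character(utils::packageVersion("cryptdrift"))),
           if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
           vapply(names(meta), function(k) sprintf("# %s: %s", k, format(meta[[k]])), character(1)))
  writeLines(hdr, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Reproduce the headline analyses
#'
#' One-command desk-scale reproduction: the analytic effective stem cell
#' numbers, ratio recovery from synthetic long-term retention data at the
#' three presets, SI/LI monoclonality at 6 weeks, and SI/LI border-clone
#' persistence at 8 weeks. Results are returned as a named list and, if
#' `out_dir` is given, written as delimited text with provenance headers.
#'
#' @param seed Integer seed for all stochastic steps.
#' @param out_dir Optional output directory.
#' @param n_clones_per_row Clones per starting row for the recovery runs.
#' @param n_crypts Crypts for the monoclonality runs.
#' @return A named list of tibbles; see Details in the package vignette.
#' @export
reproduce_analyses <- function(seed = 1L, out_dir = NULL,
                               n_clones_per_row = 500, n_crypts = 200) {
  set.seed(seed)
  g <- crypt_geometry()
  anl <- tibble(
    condition = c("SI", "LI"),
    ratio = c(2, 0.25),
    n_s = c(effective_stem_cell_number(5, 2)$n_s_rounded,
            effective_stem_cell_number(5, 0.25)$n_s_rounded),
    effective_rows = c(effective_rows(2), effective_rows(0.25)))

  recovery <- purrr::map_dfr(c("SI", "LI", "SI_LGK974"), function(cond) {
    p <- crypt_preset(cond)
    obs <- run_lineage_tracing(p, g, n_clones_per_row = n_clones_per_row,
                               record_times = c(2, 56))
    fit <- fit_ratio_longterm(retention_counts(obs, 56), n_boot = 200)
    tibble(condition = cond, true_ratio = p$ratio, ratio_hat = fit$ratio,
           ci_low = fit$ci_low, ci_high = fit$ci_high)
  })

  mono <- purrr::map_dfr(c("SI", "LI"), function(cond)
    run_monoclonal_drift(crypt_preset(cond), g, n_crypts = n_crypts, record_times = 42))

  border <- purrr::map_dfr(c("SI", "LI"), function(cond) {
    obs <- run_lineage_tracing(crypt_preset(cond), g, start_rows = band_rows(g$border_rows),
                               n_clones_per_row = n_clones_per_row, record_times = c(2, 56))
    cts <- retention_counts(obs, 56, cohort_time = 2)
    tibble(condition = cond,
           retained_fraction = sum(cts$n_retained) / sum(cts$n_clones),
           n_cohort = sum(cts$n_clones))
  })

  out <- list(effective_stem_cells = anl, ratio_recovery = recovery,
              monoclonality_6wk = mono, border_persistence_8wk = border)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      write_observations(out[[nm]], file.path(out_dir, paste0(nm, ".csv")), seed = seed)
  }
  out
}
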