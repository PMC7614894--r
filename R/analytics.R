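#' Gaussian clone-retention profile
#'
#' In the stochastic conveyor belt, the probability that a clone founded at
#' row x persists long-term in the niche falls off as a Gaussian in the
#' starting row, exp(-x^2 / (2 sigma^2)) with sigma^2 = k_r/k_d, normalised
#' to 1 at the crypt base (row 0). With no retrograde movement (ratio 0) only
#' row 0 retains.
#'
#' @param ratio Dimensionless k_r/k_d (>= 0).
#' @param rows Integer row positions (default 0:7).
#' @return A `retention_profile` tibble with columns `row`, `probability` and
#'   attribute `sigma2 = ratio`.
#' @examples
#' retention_profile(2, rows = 0:3)
#' @export
retention_profile <- function(ratio, rows = 0:7) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0)
    abort("`ratio` must be a single non-negative number", class = "cryptdrift_config_error")
  rows <- as.integer(rows)
  p <- if (ratio == 0) as.numeric(rows == 0L) else exp(-rows^2 / (2 * ratio))
  structure(tibble(row = rows, probability = p),
            sigma2 = ratio, class = c("retention_profile", class(tibble())))
}

#' Effective stem cell number
#'
#' Retrograde movement widens the band of rows whose lineages can win the
#' niche competition, giving N_s = N_g (1 + 2 sqrt(k_r/k_d)) effective stem
#' cells: the base row plus roughly 2 sigma rows' worth of cells above it.
#' At the fitted ratios this evaluates to ~19 per small-intestinal crypt
#' (N_g = 5, ratio 2) and ~10 per large-intestinal crypt (ratio 0.25).
#'
#' @param n_g Cells per row (>= 1).
#' @param ratio Dimensionless k_r/k_d (>= 0).
#' @param threshold Retention cutoff defining an effective row (default 0.05).
#' @return A `stem_cell_estimate` list: `n_g`, `ratio`, `n_s` (raw),
#'   `n_s_rounded`, `n_rows_effective`, `threshold`.
#' @examples
#' effective_stem_cell_number(5, 2)$n_s_rounded # 19
#' effective_stem_cell_number(5, 0.25)$n_s_rounded # 10
#' @export
effective_stem_cell_number <- function(n_g, ratio, threshold = 0.05) {
  if (!is.numeric(n_g) || length(n_g) != 1L || is.na(n_g) || n_g < 1)
    abort("`n_g` must be a single integer >= 1", class = "cryptdrift_config_error")
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0)
    abort("`ratio` must be a single non-negative number", class = "cryptdrift_config_error")
  n_s <- n_g * (1 + 2 * sqrt(ratio))
  structure(
    list(n_g = as.integer(n_g), ratio = ratio, n_s = n_s,
         n_s_rounded = as.integer(round(n_s)),
         n_rows_effective = effective_rows(ratio, threshold),
         threshold = threshold),
    class = "stem_cell_estimate")
}

#' @export
print.stem_cell_estimate <- function(x, ...) {
  cat(sprintf("<stem_cell_estimate> N_s = %.2f (~%d) at N_g = %d, k_r/k_d = %g; %d effective row(s) above %g%% retention\n",
              x$n_s, x$n_s_rounded, x$n_g, x$ratio, x$n_rows_effective, 100 * x$threshold))
  invisible(x)
}

#' Number of effective rows
#'
#' Counts consecutive rows from the crypt base whose normalised long-term
#' retention probability stays at or above `threshold` (5% by default,
#' corresponding to roughly 2 sigma of the positional fluctuations).
#'
#' @inheritParams effective_stem_cell_number
#' @return Integer count of effective rows (>= 1).
#' @examples
#' effective_rows(0.25) # 2: the first two rows
#' @export
effective_rows <- function(ratio, threshold = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold >= 1)
    abort("`threshold` must lie strictly between 0 and 1", class = "cryptdrift_config_error")
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0)
    abort("`ratio` must be a single non-negative number", class = "cryptdrift_config_error")
  if (ratio == 0) return(1L)
  # retention(x) >= threshold  <=>  x <= sigma * sqrt(2 log(1/threshold))
  as.integer(floor(sqrt(ratio) * sqrt(2 * log(1 / threshold)))) + 1L
}

#' Monoclonal-conversion time versus sqrt(k_r/k_d)
#'
#' Simulates the mean time for a crypt started from all-distinct labels to
#' become monoclonal over the Lgr5+ zone, across a set of ratios, and
#' regresses the mean conversion time on sqrt(ratio). The conversion time
#' grows close to linearly in sqrt(k_r/k_d), mirroring the widening of the
#' effective stem cell pool.
#'
#' @param ratios Ratios k_r/k_d to scan (all >= 0).
#' @param params Baseline [kinetic_params()]; its `k_d` sets the time scale
#'   and its `k_r` is overridden per ratio.
#' @param n_reps Simulated crypts per ratio.
#' @param geometry A [crypt_geometry()].
#' @param t_max Per-crypt simulation horizon in days (conversion times beyond
#'   it are censored and dropped with a warning).
#' @return A `fixation_scaling` list: `times` (tibble `ratio,
#'   mean_conversion_days, n`), `fit` (the `lm` of mean time on sqrt(ratio))
#'   and `r_squared`.
#' @examples
#' set.seed(1)
#' fixation_time_scaling(c(0.25, 1), n_reps = 5)$times
#' @export
fixation_time_scaling <- function(ratios, params = kinetic_params(k_d = 1.4, ratio = 0),
                                  n_reps = 100, geometry = crypt_geometry(),
                                  t_max = 2000) {
  if (any(ratios < 0) || !length(ratios))
    abort("`ratios` must be non-negative", class = "cryptdrift_config_error")
  if (n_reps < 1) abort("`n_reps` must be >= 1", class = "cryptdrift_config_error")
  band <- geometry$lgr5_rows
  times <- purrr::map_dfr(ratios, function(rho) {
    tf <- vapply(seq_len(n_reps), function(i) {
      cpp_monoclonal(geometry$n_rows, geometry$cells_per_row, params$k_d, rho * params$k_d,
                     numeric(0), band[1], band[2], t_max)$t_fix
    }, numeric(1))
    if (anyNA(tf)) warn(sprintf("%d of %d crypts not monoclonal by t_max at ratio %g",
                                sum(is.na(tf)), n_reps, rho))
    tibble(ratio = rho, mean_conversion_days = mean(tf, na.rm = TRUE), n = sum(!is.na(tf)))
  })
  out <- list(times = times, fit = NULL, r_squared = NA_real_)
  if (nrow(times) >= 2L) {
    fit <- lm(mean_conversion_days ~ sqrt(ratio), data = times)
    out$fit <- fit
    out$r_squared <- summary(fit)$r.squared
  }
  structure(out, class = "fixation_scaling")
}

#' @export
print.fixation_scaling <- function(x, ...) {
  print(x$times)
  if (!is.null(x$fit))
    cat(sprintf("linear fit: time = %.2f + %.2f * sqrt(ratio) days, R^2 = %.3f\n",
                coef(x$fit)[1], coef(x$fit)[2], x$r_squared))
  invisible(x)
}
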