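#' Aggregate clone observations into retention counts
#'
#' Collapses a `clone_observations` table to the counts consumed by
#' [fit_ratio_longterm()]: clones and retained clones per starting row at
#' `at_time`. With `cohort_time` set, the denominator follows the intravital
#' protocol in which clone positions are recorded about 48 h after induction
#' and only clones then present in the Lgr5+ zone are traced onward: clones
#' not retained at `cohort_time` are dropped.
#'
#' @param observations A `clone_observations` tibble.
#' @param at_time The observation time (days) to score retention at.
#' @param cohort_time Optional earlier time (days) defining the traced cohort.
#' @return A tibble `start_row, time_days, n_clones, n_retained`.
#' @export
retention_counts <- function(observations, at_time, cohort_time = NULL) {
  obs <- filter(observations, .data$time_days == at_time)
  if (!nrow(obs)) abort("no observations at `at_time`", class = "cryptdrift_config_error")
  if (!is.null(cohort_time)) {
    cohort <- filter(observations, .data$time_days == cohort_time, .data$retained)
    obs <- filter(obs, .data$clone_id %in% cohort$clone_id)
  }
  obs %>%
    group_by(start_row = .data$start_row, time_days = .data$time_days) %>%
    summarise(n_clones = dplyr::n(), n_retained = sum(.data$retained), .groups = "drop") %>%
    arrange(.data$start_row)
}

#' Fit k_r/k_d from long-term retention by starting row
#'
#' Maximises the binomial likelihood of the retained counts under the
#' Gaussian retention law p(row) = p0 * exp(-row^2 / (2 sigma^2)), with free
#' amplitude p0 in (0, 1] and sigma^2 >= 0, and reports ratio = sigma^2.
#' Fitting the amplitude rather than normalising the data to row 0 avoids
#' dividing by a noisy row-0 estimate. Confidence intervals come from a
#' nonparametric bootstrap over clones (percentile, `n_boot` resamples),
#' implemented as stratified multinomial resampling of the per-row retained /
#' lost counts.
#'
#' @param counts A tibble with columns `start_row`, `n_clones`, `n_retained`
#'   at a single late observation time (see [retention_counts()]), including
#'   row 0 and at least two rows with clones.
#' @param n_g Cells per row used to derive the effective stem cell number.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   before the bootstrap and recorded in the fit.
#' @return A `ratio_fit` list: `ratio` (= `sigma2`), `p0`, `n_s`, `ci_low`,
#'   `ci_high`, `n_boot`, `boot_ratios`, `loss` (negative log-likelihood),
#'   `boundary` flag, `counts`, `seed`.
#' @examples
#' counts <- tibble::tibble(start_row = 0:3, n_clones = 500,
#'                          n_retained = c(180, 95, 25, 4))
#' fit <- fit_ratio_longterm(counts, n_boot = 50)
#' fit$ratio
#' @export
fit_ratio_longterm <- function(counts, n_g = 5, n_boot = 1000, seed = NULL) {
  counts <- arrange(as_tibble(counts), .data$start_row)
  if (!all(c("start_row", "n_clones", "n_retained") %in% names(counts)))
    abort("`counts` needs columns start_row, n_clones, n_retained",
          class = "cryptdrift_config_error")
  if (!0L %in% counts$start_row[counts$n_clones > 0])
    abort("row 0 must be observed", class = "cryptdrift_config_error")
  if (sum(counts$n_clones > 0) < 2L)
    abort("need clones at >= 2 distinct starting rows", class = "cryptdrift_config_error")
  if (any(counts$n_retained > counts$n_clones) || any(counts$n_retained < 0))
    abort("retained counts must lie in [0, n_clones]", class = "cryptdrift_config_error")
  if (sum(counts$n_retained) == 0)
    abort("all-zero retention: ratio unidentifiable", class = "cryptdrift_unidentifiable_error")
  if (!is.null(seed)) set.seed(seed)

  est <- gaussian_binom_mle(counts)
  boot <- boot_ratios(counts, n_boot)
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  structure(
    list(ratio = est$sigma2, sigma2 = est$sigma2, p0 = est$p0,
         n_s = effective_stem_cell_number(n_g, est$sigma2)$n_s,
         n_g = n_g, ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, boot_ratios = boot, loss = est$nll,
         boundary = est$boundary, counts = counts, seed = seed),
    class = "ratio_fit")
}

# binomial MLE of (p0, sigma2); sigma2 optimised on the log scale with a
# boundary flag when the profile degenerates to row-0-only retention
gaussian_binom_mle <- function(counts) {
  x <- counts$start_row
  if (sum(counts$n_retained[x > 0]) == 0) {
    p0 <- sum(counts$n_retained[x == 0]) / sum(counts$n_clones[x == 0])
    nll <- -sum(dbinom(counts$n_retained, counts$n_clones,
                       ifelse(x == 0, max(p0, 1e-12), 1e-12), log = TRUE))
    return(list(p0 = p0, sigma2 = 0, nll = nll, boundary = TRUE))
  }
  nll <- function(par) {
    p0 <- plogis(par[1]); s2 <- exp(par[2])
    p <- pmin(pmax(p0 * exp(-x^2 / (2 * s2)), 1e-12), 1 - 1e-12)
    -sum(dbinom(counts$n_retained, counts$n_clones, p, log = TRUE))
  }
  p0_init <- max(min(sum(counts$n_retained[x == 0]) / max(sum(counts$n_clones[x == 0]), 1), 0.99), 0.01)
  o <- optim(c(qlogis(p0_init), 0), nll, method = "Nelder-Mead",
             control = list(maxit = 500, reltol = 1e-10))
  list(p0 = plogis(o$par[1]), sigma2 = exp(o$par[2]), nll = o$value,
       boundary = exp(o$par[2]) < 1e-4)
}

# nonparametric bootstrap over clones: within each starting row, clones are
# exchangeable Bernoulli records, so resampling clones i.i.d. is equivalent
# to redrawing the retained count from Binomial(n_row, phat_row)
boot_ratios <- function(counts, n_boot) {
  keep <- counts$n_clones > 0
  cc <- counts[keep, ]
  vapply(seq_len(n_boot), function(b) {
    bc <- cc
    bc$n_retained <- rbinom(nrow(cc), cc$n_clones, cc$n_retained / cc$n_clones)
    if (sum(bc$n_retained) == 0) return(NA_real_)
    gaussian_binom_mle(bc)$sigma2
  }, numeric(1))
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("<ratio_fit> k_r/k_d = %.3f (95%% CI %.3f-%.3f, %d bootstrap resamples)\n",
              x$ratio, x$ci_low, x$ci_high, x$n_boot))
  cat(sprintf("  p0 = %.3f, N_s = %.1f at N_g = %d, -logLik = %.2f%s\n",
              x$p0, x$n_s, x$n_g, x$loss,
              if (x$boundary) " [sigma^2 at boundary 0]" else ""))
  invisible(x)
}

#' @rdname fit_ratio_longterm
#' @param x A `ratio_fit`.
#' @param ... Unused.
#' @export
tidy.ratio_fit <- function(x, ...) {
  tibble(term = c("ratio", "p0"),
         estimate = c(x$ratio, x$p0),
         conf.low = c(x$ci_low, NA_real_),
         conf.high = c(x$ci_high, NA_real_))
}

#' @rdname fit_ratio_longterm
#' @export
glance.ratio_fit <- function(x, ...) {
  tibble(ratio = x$ratio, ci_low = x$ci_low, ci_high = x$ci_high,
         p0 = x$p0, n_s = x$n_s, logLik = -x$loss, n_boot = x$n_boot,
         boundary = x$boundary,
         n_clones = sum(x$counts$n_clones))
}

#' Predicted retention profile with bootstrap band
#'
#' Evaluates the fitted Gaussian retention law (normalised to row 0) and a
#' 95% band from the bootstrap replicate curves.
#'
#' @param fit A `ratio_fit`.
#' @param rows Rows to predict at.
#' @return A tibble `row, probability, lower, upper`.
#' @export
predict_retention <- function(fit, rows = 0:3) {
  rows <- as.integer(rows)
  central <- retention_profile(fit$ratio, rows)$probability
  reps <- vapply(fit$boot_ratios[!is.na(fit$boot_ratios)],
                 function(s2) retention_profile(s2, rows)$probability,
                 numeric(length(rows)))
  reps <- matrix(reps, nrow = length(rows))
  tibble(row = rows, probability = central,
         lower = apply(reps, 1L, quantile, 0.025),
         upper = apply(reps, 1L, quantile, 0.975))
}

#' Fit the division rate from short-term retention dynamics
#'
#' With the ratio k_r/k_d fixed, the division rate k_d sets the absolute time
#' scale of the early retention dynamics. A grid of candidate k_d values is
#' scored by simulating the per-row retention trajectory at each candidate
#' (k_r = ratio * k_d) and minimising the squared error against the observed
#' trajectories.
#'
#' @param observations A `clone_observations` tibble covering >= 2
#'   observation times (e.g. days 1-4).
#' @param ratio Fixed dimensionless k_r/k_d.
#' @param kd_grid Candidate division rates (per day).
#' @param n_sim_per_grid Simulated clones per starting row per candidate.
#' @param geometry A [crypt_geometry()].
#' @return A `kd_fit` list: `k_d`, `loss` (at the optimum), `grid` (tibble
#'   `k_d, loss`), `ratio`.
#' @export
fit_kd_shortterm <- function(observations, ratio, kd_grid = c(0.7, 1, 1.4, 2, 2.8),
                             n_sim_per_grid = 200, geometry = crypt_geometry()) {
  if (ratio < 0) abort("`ratio` must be >= 0", class = "cryptdrift_config_error")
  times <- sort(unique(observations$time_days))
  if (length(times) < 2L)
    abort("k_d is unidentifiable from a single observation time",
          class = "cryptdrift_unidentifiable_error")
  obs <- observations %>%
    group_by(.data$start_row, .data$time_days) %>%
    summarise(p = mean(.data$retained), .groups = "drop")
  start_rows <- sort(unique(obs$start_row))
  grid <- purrr::map_dfr(kd_grid, function(kd) {
    sim <- run_lineage_tracing(kinetic_params(k_d = kd, ratio = ratio), geometry,
                               start_rows = start_rows,
                               n_clones_per_row = n_sim_per_grid,
                               record_times = times) %>%
      group_by(.data$start_row, .data$time_days) %>%
      summarise(p_sim = mean(.data$retained), .groups = "drop")
    j <- left_join(obs, sim, by = c("start_row", "time_days"))
    tibble(k_d = kd, loss = sum((j$p - j$p_sim)^2))
  })
  best <- grid$k_d[which.min(grid$loss)]
  structure(list(k_d = best, loss = min(grid$loss), grid = grid, ratio = ratio),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> k_d = %g/day (grid %s), ratio fixed at %g, loss = %.4f\n",
              x$k_d, paste(x$grid$k_d, collapse = ", "), x$ratio, x$loss))
  invisible(x)
}

#' @rdname fit_kd_shortterm
#' @param x A `kd_fit`.
#' @param ... Unused.
#' @export
glance.kd_fit <- function(x, ...) {
  tibble(k_d = x$k_d, loss = x$loss, ratio = x$ratio, grid_size = nrow(x$grid))
}
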