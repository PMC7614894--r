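#' Study design for synthetic lineage-tracing data
#'
#' Bundles the experimental design of the intravital study the generator
#' emulates: a long-term tracing arm observed at ~48 h and 8 weeks, a
#' short-term arm observed daily on days 1-4, whole-mount monoclonality
#' counts at weeks 1-8, and an ablation-recovery arm. Default arm sizes
#' follow the study (long-term: SI 267 clones / 6 mice, LI 294 / 6;
#' short-term: SI 305 / 9, LI 311 / 5); kinetic parameters default to the
#' fitted presets.
#'
#' @param arms A tibble with columns `condition`, `ratio`, `k_d`,
#'   `n_long`, `mice_long`, `n_short`, `mice_short`.
#' @param long_term_times Observation days of the long-term arm.
#' @param short_term_times Observation days of the short-term arm.
#' @param monoclonality_times Observation days of the whole-mount arm.
#' @param n_crypts_monoclonality Crypts scored per condition per time.
#' @param ablation_times Observation days of the ablation arm.
#' @param n_crypts_ablation Ablated crypts per condition.
#' @param start_row_weighting `"uniform"` or `"lgr5-graded"` (see
#'   [allocate_start_rows()]).
#' @param kd_mouse_cv Coefficient of variation of an optional per-mouse
#'   log-normal jitter on k_d (0 = none, the default: pure sampling noise).
#' @param geometry A [crypt_geometry()].
#' @param seed Integer seed; mandatory, recorded in every output table.
#' @return A `study_design` list.
#' @export
study_design <- function(arms = default_arms(),
                         long_term_times = c(2, 56),
                         short_term_times = 1:4,
                         monoclonality_times = 7 * c(1, 2, 4, 6, 8),
                         n_crypts_monoclonality = 120,
                         ablation_times = c(1, 2, 4, 7, 15),
                         n_crypts_ablation = 100,
                         start_row_weighting = c("uniform", "lgr5-graded"),
                         kd_mouse_cv = 0,
                         geometry = crypt_geometry(),
                         seed = 1L) {
  arms <- as_tibble(arms)
  need <- c("condition", "ratio", "k_d", "n_long", "mice_long", "n_short", "mice_short")
  if (!all(need %in% names(arms)) || !nrow(arms))
    abort("`arms` needs columns condition, ratio, k_d, n_long, mice_long, n_short, mice_short",
          class = "cryptdrift_config_error")
  if (any(arms$n_long < 1) || any(arms$n_short < 1))
    abort("every arm needs at least one clone", class = "cryptdrift_config_error")
  if (is.unsorted(long_term_times) || is.unsorted(short_term_times))
    abort("observation times must be sorted ascending", class = "cryptdrift_config_error")
  if (is.null(seed) || is.na(seed))
    abort("`seed` is mandatory", class = "cryptdrift_config_error")
  structure(
    list(arms = arms, long_term_times = as.numeric(long_term_times),
         short_term_times = as.numeric(short_term_times),
         monoclonality_times = as.numeric(monoclonality_times),
         n_crypts_monoclonality = as.integer(n_crypts_monoclonality),
         ablation_times = as.numeric(ablation_times),
         n_crypts_ablation = as.integer(n_crypts_ablation),
         start_row_weighting = match.arg(start_row_weighting),
         kd_mouse_cv = kd_mouse_cv,
         geometry = geometry, seed = as.integer(seed)),
    class = "study_design")
}

default_arms <- function() {
  tibble(condition = c("SI", "LI"),
         ratio = c(2, 0.25), k_d = c(1.4, 1.4),
         n_long = c(267L, 294L), mice_long = c(6L, 6L),
         n_short = c(305L, 311L), mice_short = c(9L, 5L))
}

#' Allocate clone starting rows
#'
#' Induction hits individual Lgr5-expressing cells, so starting rows are
#' drawn from the Lgr5+ zone: `"uniform"` spreads clones evenly over its
#' rows; `"lgr5-graded"` weights rows by the qualitative expression gradient
#' (high in the centre rows, intermediate in the border rows).
#'
#' @param n_clones Number of clones (>= 0).
#' @param geometry A [crypt_geometry()].
#' @param weighting `"uniform"` or `"lgr5-graded"`.
#' @param graded_weights Relative weights `c(centre, border)` used by the
#'   graded scheme.
#' @return Integer vector of starting rows, length `n_clones`.
#' @export
allocate_start_rows <- function(n_clones, geometry = crypt_geometry(),
                                weighting = c("uniform", "lgr5-graded"),
                                graded_weights = c(centre = 2, border = 1)) {
  weighting <- match.arg(weighting)
  if (n_clones == 0) return(integer(0))
  rows <- band_rows(geometry$lgr5_rows)
  w <- rep(1, length(rows))
  if (weighting == "lgr5-graded") {
    w <- ifelse(rows %in% band_rows(geometry$centre_rows),
                graded_weights[["centre"]], graded_weights[["border"]])
  }
  sample(rows, n_clones, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic study bundle
#'
#' Simulates the full study design: per-clone trajectories drawn from the
#' lattice simulator at each arm's parameters, observed on the design's
#' schedule, with clones allocated uniformly to mice. The same seed always
#' yields an identical bundle.
#'
#' @param design A [study_design()].
#' @return A `study_bundle` list of tibbles: `long_term` and `short_term`
#'   (clone-observation schema plus `mouse_id` and `seed`), `monoclonality`
#'   (`condition, time_days, fraction_monoclonal, n_crypts, seed`),
#'   `ablation` (the [run_ablation_recovery()] summary plus `seed`), and
#'   `manifest` (arm parameters, sizes and the seed).
#' @examples
#' \donttest{
#' d <- study_design(seed = 7)
#' b <- generate_study(d)
#' dplyr::count(b$long_term, condition, time_days)
#' }
#' @export
generate_study <- function(design) {
  if (!inherits(design, "study_design"))
    abort("`design` must be a study_design object", class = "cryptdrift_config_error")
  set.seed(design$seed)
  g <- design$geometry

  trace_arm <- function(arm, n, n_mice, times) {
    kd_mouse <- rep(arm$k_d, n_mice)
    if (design$kd_mouse_cv > 0) {
      sdlog <- sqrt(log(1 + design$kd_mouse_cv^2))
      kd_mouse <- arm$k_d * rlnorm(n_mice, -sdlog^2 / 2, sdlog)
    }
    mouse <- sample.int(n_mice, n, replace = TRUE)
    start <- allocate_start_rows(n, g, design$start_row_weighting)
    trace_and_score(kinetic_params(k_d = arm$k_d, ratio = arm$ratio), g,
                    start, times, arm$condition,
                    mouse_id = mouse, kd_per_clone = kd_mouse[mouse]) %>%
      mutate(seed = design$seed)
  }

  long_term <- purrr::map_dfr(seq_len(nrow(design$arms)), function(a)
    trace_arm(design$arms[a, ], design$arms$n_long[a], design$arms$mice_long[a],
              design$long_term_times))
  short_term <- purrr::map_dfr(seq_len(nrow(design$arms)), function(a)
    trace_arm(design$arms[a, ], design$arms$n_short[a], design$arms$mice_short[a],
              design$short_term_times))

  monoclonality <- purrr::map_dfr(seq_len(nrow(design$arms)), function(a) {
    arm <- design$arms[a, ]
    run_monoclonal_drift(kinetic_params(k_d = arm$k_d, ratio = arm$ratio), g,
                         n_crypts = design$n_crypts_monoclonality,
                         record_times = design$monoclonality_times,
                         condition = arm$condition) %>%
      mutate(seed = design$seed)
  })

  ablation <- purrr::map_dfr(seq_len(nrow(design$arms)), function(a) {
    arm <- design$arms[a, ]
    run_ablation_recovery(kinetic_params(k_d = arm$k_d, ratio = arm$ratio), g,
                          n_crypts = design$n_crypts_ablation,
                          record_times = design$ablation_times,
                          condition = arm$condition)$summary %>%
      mutate(seed = design$seed)
  })

  manifest <- design$arms %>%
    mutate(seed = design$seed,
           start_row_weighting = design$start_row_weighting,
           kd_mouse_cv = design$kd_mouse_cv)

  structure(list(long_term = long_term, short_term = short_term,
                 monoclonality = monoclonality, ablation = ablation,
                 manifest = manifest),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> long-term %d obs, short-term %d obs, %d monoclonality points, seed %d\n",
              nrow(x$long_term), nrow(x$short_term), nrow(x$monoclonality),
              x$manifest$seed[1]))
  invisible(x)
}
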