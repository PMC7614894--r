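#' In-silico lineage tracing
#'
#' Emulates single-cell labelling: each clone gets its own crypt, one cell at
#' the given starting row is relabelled at t = 0 on an unlabelled background,
#' and the clone's occupancy is scored at each record time. A clone is
#' `retained` while it keeps at least one cell in the Lgr5+ zone, `in_centre`
#' / `in_border` while it has a cell in the respective sub-band.
#'
#' @param params A [kinetic_params()] (use [crypt_preset()] for the fitted
#'   conditions).
#' @param geometry A [crypt_geometry()].
#' @param start_rows Starting rows to induce at (0-based, inside the lattice).
#' @param n_clones_per_row Clones per starting row (0 gives an empty table).
#' @param record_times Observation times in days (sorted).
#' @param condition Condition tag stored in the output (defaults to the
#'   preset name if `params` carries one, else `"custom"`).
#'
#' @return A `clone_observations` tibble, one row per clone per record time:
#'   `clone_id, condition, start_row, time_days, n_cells, retained,
#'   in_centre, in_border, fragmented` plus list-column `cells_by_row`
#'   (integer counts by lattice row).
#' @examples
#' set.seed(1)
#' run_lineage_tracing(crypt_preset("LI"), start_rows = 0, n_clones_per_row = 3,
#'                     record_times = c(2, 7))
#' @export
run_lineage_tracing <- function(params, geometry = crypt_geometry(),
                                start_rows = band_rows(geometry$lgr5_rows),
                                n_clones_per_row = 100,
                                record_times = c(2, 56),
                                condition = NULL) {
  start_rows <- as.integer(start_rows)
  if (any(start_rows < 0L) || any(start_rows >= geometry$n_rows))
    abort("`start_rows` must lie inside the lattice", class = "cryptdrift_config_error")
  if (n_clones_per_row < 0) abort("`n_clones_per_row` must be >= 0", class = "cryptdrift_config_error")
  record_times <- sort(as.numeric(record_times))
  condition <- condition %||% attr(params, "condition") %||% "custom"
  if (n_clones_per_row == 0L || !length(start_rows)) return(empty_observations())
  start <- rep(start_rows, each = n_clones_per_row)
  trace_and_score(params, geometry, start, record_times, condition)
}

# simulate one crypt per clone and score all observations vectorized;
# counts stack: [clone x record time x lattice row]
trace_and_score <- function(params, geometry, start, record_times, condition,
                            mouse_id = NULL, kd_per_clone = NULL) {
  n <- length(start)
  nt <- length(record_times)
  cols <- sample.int(geometry$cells_per_row, n, replace = TRUE) - 1L
  counts <- array(0L, dim = c(n, nt, geometry$n_rows))
  for (i in seq_len(n)) {
    kd <- if (is.null(kd_per_clone)) params$k_d else kd_per_clone[i]
    kr <- kd * params$ratio
    counts[i, , ] <- cpp_trace_clone(geometry$n_rows, geometry$cells_per_row,
                                     start[i], cols[i], kd, kr, record_times)
  }
  centre <- band_rows(geometry$centre_rows) + 1L
  border <- band_rows(geometry$border_rows) + 1L
  flat <- matrix(aperm(counts, c(2, 1, 3)), nrow = n * nt) # row = (time within clone)
  in_centre <- rowSums(flat[, centre, drop = FALSE]) > 0L
  in_border <- rowSums(flat[, border, drop = FALSE]) > 0L
  obs <- tibble(
    clone_id = rep(seq_len(n), each = nt),
    condition = condition,
    start_row = rep(as.integer(start), each = nt),
    time_days = rep(record_times, times = n),
    n_cells = as.integer(rowSums(flat)),
    retained = in_centre | in_border,
    in_centre = in_centre,
    in_border = in_border,
    fragmented = vapply(seq_len(n * nt), function(k)
      rows_fragmented(which(flat[k, ] > 0L) - 1L), logical(1)),
    cells_by_row = lapply(seq_len(n * nt), function(k) flat[k, ])
  )
  if (!is.null(mouse_id)) obs$mouse_id <- rep(mouse_id, each = nt)
  class(obs) <- c("clone_observations", class(obs))
  obs
}

empty_observations <- function() {
  obs <- tibble(clone_id = integer(), condition = character(), start_row = integer(),
                time_days = numeric(), n_cells = integer(), retained = logical(),
                in_centre = logical(), in_border = logical(), fragmented = logical(),
                cells_by_row = list())
  class(obs) <- c("clone_observations", class(obs))
  obs
}

rows_fragmented <- function(rows_occupied) {
  if (length(rows_occupied) < 2L) return(FALSE)
  any(diff(sort(rows_occupied)) > 1L)
}

#' Is a clone fragmented?
#'
#' A clone is fragmented when the set of rows it occupies is non-contiguous:
#' at least one row strictly between two occupied rows contains none of its
#' cells. Splits within a row are not counted.
#'
#' @param state A `crypt_state`.
#' @param clone_label The lineage label to test.
#' @param geometry Unused (the state carries its geometry); kept for call
#'   symmetry with the other scoring helpers.
#' @return `TRUE`/`FALSE`.
#' @examples
#' st <- build_homeostatic_state(labelling = "single-label")
#' is_fragmented(st, 0)
#' @export
is_fragmented <- function(state, clone_label, geometry = state_geometry(state)) {
  hit <- which(apply(unclass(state) == clone_label, 1L, any))
  if (!length(hit)) abort("clone is extinct", class = "cryptdrift_logic_error")
  rows_fragmented(hit - 1L)
}

#' Compartment transition summary
#'
#' Per condition, starting compartment and time: the fraction of clones with
#' any cell in the centre rows (`p_centre`), in the border rows but not the
#' centre (`p_border_only`), and with no cell in the Lgr5+ zone (`p_lost`).
#' The three sum to 1.
#'
#' @param observations A `clone_observations` tibble.
#' @param geometry The [crypt_geometry()] used to classify starting rows.
#' @return A tibble `condition, start_compartment, time_days, n_clones,
#'   p_centre, p_border_only, p_lost`.
#' @export
compartment_transition_summary <- function(observations, geometry = crypt_geometry()) {
  if (!nrow(observations))
    abort("`observations` is empty", class = "cryptdrift_empty_error")
  centre <- band_rows(geometry$centre_rows)
  border <- band_rows(geometry$border_rows)
  observations %>%
    mutate(start_compartment = dplyr::case_when(
      .data$start_row %in% centre ~ "centre",
      .data$start_row %in% border ~ "border",
      TRUE ~ "beyond")) %>%
    group_by(.data$condition, .data$start_compartment, .data$time_days) %>%
    summarise(n_clones = dplyr::n(),
              p_centre = mean(.data$in_centre),
              p_border_only = mean(.data$in_border & !.data$in_centre),
              p_lost = mean(!.data$retained),
              .groups = "drop")
}

#' Monoclonal drift of whole crypts
#'
#' Crypts are initialised with every cell a distinct lineage; a crypt counts
#' as monoclonal at time t when a single lineage occupies every site of
#' `monoclonal_band` (the Lgr5+ zone by default).
#'
#' @inheritParams run_lineage_tracing
#' @param n_crypts Number of independent crypts (>= 1).
#' @param record_times Observation times in days.
#' @param monoclonal_band Inclusive row band judged for monoclonality.
#' @return A `monoclonality_series` tibble: `condition, time_days,
#'   fraction_monoclonal, n_crypts`.
#' @examples
#' set.seed(1)
#' run_monoclonal_drift(crypt_preset("LI"), n_crypts = 10, record_times = c(7, 14))
#' @export
run_monoclonal_drift <- function(params, geometry = crypt_geometry(), n_crypts = 100,
                                 record_times = 7 * (1:8),
                                 monoclonal_band = geometry$lgr5_rows,
                                 condition = NULL) {
  if (n_crypts < 1) abort("`n_crypts` must be >= 1", class = "cryptdrift_config_error")
  record_times <- sort(as.numeric(record_times))
  condition <- condition %||% attr(params, "condition") %||% "custom"
  band <- as.integer(monoclonal_band)
  flags <- vapply(seq_len(n_crypts), function(i) {
    as.logical(cpp_monoclonal(geometry$n_rows, geometry$cells_per_row,
                              params$k_d, params$k_r, record_times,
                              band[1], band[2], max(record_times))$monoclonal)
  }, logical(length(record_times)))
  flags <- matrix(flags, nrow = length(record_times))
  out <- tibble(condition = condition, time_days = record_times,
                fraction_monoclonal = rowMeans(flags), n_crypts = n_crypts)
  class(out) <- c("monoclonality_series", class(out))
  out
}

#' Clone fragmentation assay
#'
#' Induces clones as in [run_lineage_tracing()] (starting rows uniform over
#' the Lgr5+ zone), scores them at time `t`, and reports the fraction of
#' fragmented clones among survivors with at least 2 cells.
#'
#' @inheritParams run_lineage_tracing
#' @param n_clones Number of induced clones (> 0).
#' @param t Scoring time in days (> 0).
#' @return A list: `probability`, `n_scored` (surviving multi-cell clones),
#'   `n_fragmented`, `n_clones`, `condition`, `t`.
#' @export
run_fragmentation_assay <- function(params, geometry = crypt_geometry(),
                                    n_clones = 500, t = 7, condition = NULL) {
  if (t <= 0) abort("`t` must be positive", class = "cryptdrift_config_error")
  if (n_clones < 1)
    abort("fragmentation probability is undefined without clones",
          class = "cryptdrift_config_error")
  condition <- condition %||% attr(params, "condition") %||% "custom"
  lgr5 <- band_rows(geometry$lgr5_rows)
  start <- sample(lgr5, n_clones, replace = TRUE)
  res <- vapply(start, function(sr) {
    counts <- cpp_trace_clone(geometry$n_rows, geometry$cells_per_row, sr,
                              sample.int(geometry$cells_per_row, 1L) - 1L,
                              params$k_d, params$k_r, t)
    n <- sum(counts[1L, ])
    c(multi = n >= 2L, frag = n >= 2L && rows_fragmented(which(counts[1L, ] > 0L) - 1L))
  }, logical(2))
  n_scored <- sum(res["multi", ])
  n_frag <- sum(res["frag", ])
  list(probability = if (n_scored) n_frag / n_scored else NA_real_,
       n_scored = n_scored, n_fragmented = n_frag,
       n_clones = n_clones, condition = condition, t = t)
}

#' Ablation-recovery experiment
#'
#' Each crypt starts fully occupied, its Lgr5+ zone is emptied at t = 0
#' (targeted ablation), and the vacancy-filling dynamics (relocation into
#' vacancies; division daughters filling adjacent vacancies without push-up)
#' are simulated. The position of the lowest occupied row tracks the
#' regeneration of the stem-cell compartment.
#'
#' @inheritParams run_monoclonal_drift
#' @param record_times Observation times in days.
#' @return An `ablation_trajectory` list with tibbles `per_crypt`
#'   (`condition, crypt_id, time_days, lowest_row`) and `summary`
#'   (`condition, time_days, mean_lowest_row`, and `p_reached_row<r>`
#'   columns: the fraction of crypts with at least one cell at or below each
#'   row of the ablated band).
#' @examples
#' set.seed(1)
#' run_ablation_recovery(crypt_preset("SI"), n_crypts = 5, record_times = c(1, 2))$summary
#' @export
run_ablation_recovery <- function(params, geometry = crypt_geometry(), n_crypts = 100,
                                  record_times = c(1, 2, 4, 7, 15),
                                  condition = NULL) {
  if (n_crypts < 1) abort("`n_crypts` must be >= 1", class = "cryptdrift_config_error")
  record_times <- sort(as.numeric(record_times))
  condition <- condition %||% attr(params, "condition") %||% "custom"
  band <- geometry$lgr5_rows
  per_crypt <- purrr::map_dfr(seq_len(n_crypts), function(i) {
    st <- ablate(build_homeostatic_state(geometry, "single-label"), band)
    res <- cpp_simulate(unclass(st), params$k_d, params$k_r,
                        max(record_times), record_times, FALSE)
    low <- vapply(res$snapshots, function(m) {
      occ <- which(apply(m >= 0L, 1L, any))
      if (length(occ)) occ[1] - 1L else NA_integer_
    }, integer(1))
    tibble(condition = condition, crypt_id = i, time_days = record_times, lowest_row = low)
  })
  summ <- per_crypt %>%
    group_by(.data$condition, .data$time_days) %>%
    summarise(mean_lowest_row = mean(.data$lowest_row), .groups = "drop")
  for (r in band_rows(band)) {
    frac <- per_crypt %>%
      group_by(.data$time_days) %>%
      summarise(p = mean(.data$lowest_row <= r), .groups = "drop")
    summ[[sprintf("p_reached_row%d", r)]] <- frac$p
  }
  structure(list(per_crypt = per_crypt, summary = summ),
            class = "ablation_trajectory", geometry = geometry, params = params)
}

#' @export
print.ablation_trajectory <- function(x, ...) {
  cat(sprintf("<ablation_trajectory> %d crypts\n", max(x$per_crypt$crypt_id)))
  print(x$summary)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
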