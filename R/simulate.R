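#' Total event rate of a crypt state
#'
#' Division and relocation are per-cell rates applied uniformly to every
#' occupied site, so the total propensity is `n_occupied * (k_d + k_r)`.
#'
#' @param state A `crypt_state`.
#' @param params A [kinetic_params()].
#' @return Total event rate (events per day).
#' @examples
#' total_event_rate(build_homeostatic_state(), crypt_preset("SI"))
#' @export
total_event_rate <- function(state, params) {
  sum(unclass(state) >= 0L) * (params$k_d + params$k_r)
}

#' Apply a single division event
#'
#' The label at `site` is duplicated; the daughter is inserted at a uniformly
#' chosen neighbouring site (left, right -- cyclic -- or directly above), and
#' every occupied cell in the insertion column at or above the insertion row
#' shifts up one row. A cell pushed past the top row exits; in ablation mode
#' a vacant insertion site is filled with no push-up, and a mid-column
#' vacancy absorbs the shift. Insertion above the top row means the daughter
#' exits immediately.
#'
#' @param state A `crypt_state`.
#' @param site `c(row, column)`, 0-based; must be occupied.
#' @return The updated `crypt_state`.
#' @export
apply_division <- function(state, site) {
  check_site(state, site)
  occ <- cpp_apply_division(unclass(state), site[1], site[2])
  new_crypt_state(occ, state_geometry(state), time = attr(state, "time"))
}

#' Apply a single relocation event
#'
#' Swaps the contents of `site` with a uniformly chosen existing lattice
#' neighbour (left, right, up, down; row 0 has no down-neighbour). Swapping
#' with a vacancy moves the cell into it.
#'
#' @inheritParams apply_division
#' @return The updated `crypt_state`.
#' @export
apply_relocation <- function(state, site) {
  check_site(state, site)
  occ <- cpp_apply_relocation(unclass(state), site[1], site[2])
  new_crypt_state(occ, state_geometry(state), time = attr(state, "time"))
}

check_site <- function(state, site) {
  g <- state_geometry(state)
  if (length(site) != 2L || site[1] < 0 || site[1] >= g$n_rows ||
      site[2] < 0 || site[2] >= g$cells_per_row)
    abort("`site` must be c(row, column) inside the lattice", class = "cryptdrift_config_error")
  if (unclass(state)[site[1] + 1L, site[2] + 1L] < 0L)
    abort("event applied to a vacant site", class = "cryptdrift_logic_error")
  invisible(TRUE)
}

#' Simulate crypt dynamics
#'
#' Exact continuous-time (Gillespie) simulation of the stochastic conveyor
#' belt: waiting times are exponential with the total propensity
#' [total_event_rate()], the event kind is chosen proportionally to the
#' per-cell rates, and the site uniformly over occupied cells. Works in both
#' homeostasis and ablation mode.
#'
#' @param state Initial `crypt_state`.
#' @param params A [kinetic_params()].
#' @param duration Days to simulate (>= 0).
#' @param record_times Sorted snapshot times within `[0, duration]`; defaults
#'   to `duration` only.
#' @param record_events If `TRUE`, also return the full event log.
#'
#' @return A `crypt_trajectory` list with elements
#'   \describe{
#'     \item{snapshots}{tibble `time, row, column, label` across record times.}
#'     \item{states}{list of `crypt_state` objects, one per record time.}
#'     \item{events}{tibble `time, kind, site_row, site_col, target_row,
#'       target_col` (only if `record_events`); for divisions the target is
#'       the insertion site.}
#'   }
#' @examples
#' set.seed(1)
#' traj <- simulate_crypt(build_homeostatic_state(), crypt_preset("LI"), duration = 1)
#' traj$snapshots
#' @export
simulate_crypt <- function(state, params, duration,
                           record_times = duration, record_events = FALSE) {
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) || duration < 0)
    abort("`duration` must be a single non-negative number of days",
          class = "cryptdrift_config_error")
  record_times <- sort(as.numeric(record_times))
  if (length(record_times) && (record_times[1] < 0 || record_times[length(record_times)] > duration))
    abort("`record_times` must lie within [0, duration]", class = "cryptdrift_config_error")
  g <- state_geometry(state)
  t0 <- attr(state, "time")
  res <- cpp_simulate(unclass(state), params$k_d, params$k_r, duration, record_times, record_events)
  states <- lapply(seq_along(record_times), function(i)
    new_crypt_state(res$snapshots[[i]], g, time = t0 + record_times[i]))
  snapshots <- bind_rows(lapply(states, as_tibble))
  out <- list(snapshots = snapshots, states = states)
  if (record_events) {
    ev <- as_tibble(res$events)
    ev$kind <- c("division", "relocation")[ev$kind + 1L]
    ev$time <- ev$time + t0
    out$events <- ev
  }
  structure(out, class = "crypt_trajectory", geometry = g, params = params)
}

#' @export
print.crypt_trajectory <- function(x, ...) {
  cat(sprintf("<crypt_trajectory> %d snapshot(s)%s\n", length(x$states),
              if (is.null(x$events)) "" else sprintf(", %d events logged", nrow(x$events))))
  invisible(x)
}
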