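#' Build a fully occupied crypt state
#'
#' Creates a homeostatic (fully occupied) lattice. `"all-distinct"` gives
#' every site its own lineage label (0..N-1), the initial condition of the
#' monoclonal-drift experiments; `"single-label"` fills the lattice with
#' label 0, the unlabelled background on which lineage tracing induces a
#' single marked cell.
#'
#' @param geometry A [crypt_geometry()].
#' @param labelling `"all-distinct"` or `"single-label"`.
#'
#' @return A `crypt_state`: an integer label matrix (rows x columns, row 1 of
#'   the matrix = crypt base row 0) with attributes `geometry`, `time` and
#'   `mode` (`"homeostasis"` or `"ablation"`). Vacancies are coded -1 and
#'   only arise in ablation mode.
#' @examples
#' st <- build_homeostatic_state(crypt_geometry(), "all-distinct")
#' dplyr::n_distinct(as_tibble(st)$label)
#' @export
build_homeostatic_state <- function(geometry = crypt_geometry(),
                                    labelling = c("all-distinct", "single-label")) {
  if (!inherits(geometry, "crypt_geometry"))
    abort("`geometry` must be a crypt_geometry object", class = "cryptdrift_config_error")
  labelling <- match.arg(labelling)
  n <- geometry$n_rows * geometry$cells_per_row
  labs <- if (labelling == "all-distinct") seq_len(n) - 1L else rep(0L, n)
  occ <- matrix(labs, nrow = geometry$n_rows, ncol = geometry$cells_per_row, byrow = TRUE)
  new_crypt_state(occ, geometry, time = 0)
}

new_crypt_state <- function(occ, geometry, time = 0) {
  storage.mode(occ) <- "integer"
  mode <- if (any(occ < 0L)) "ablation" else "homeostasis"
  structure(occ, geometry = geometry, time = time, mode = mode,
            class = c("crypt_state", class(occ)))
}

#' @export
print.crypt_state <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<crypt_state> %d x %d, t = %g d, mode = %s, %d lineages\n",
              g$n_rows, g$cells_per_row, attr(x, "time"), attr(x, "mode"),
              length(unique(x[x >= 0L]))))
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim")]
  rownames(m) <- paste0("row", seq_len(nrow(m)) - 1L)
  print(m[rev(seq_len(nrow(m))), , drop = FALSE])
  invisible(x)
}

#' Tidy view of a crypt state
#'
#' @param x A `crypt_state`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `row`, `column`, `label` (label is
#'   `NA` for vacant sites). Rows and columns are 0-based, row 0 = crypt base.
#' @export
as_tibble.crypt_state <- function(x, ...) {
  g <- attr(x, "geometry")
  lab <- as.integer(x)
  tibble(
    time = attr(x, "time"),
    row = rep(seq_len(g$n_rows) - 1L, times = g$cells_per_row),
    column = rep(seq_len(g$cells_per_row) - 1L, each = g$n_rows),
    label = ifelse(lab < 0L, NA_integer_, lab)
  ) %>% arrange(.data$row, .data$column)
}

state_geometry <- function(state) attr(state, "geometry")

#' Is a row band monoclonal?
#'
#' @param state A `crypt_state`.
#' @param band Inclusive row band, default the Lgr5+ zone.
#' @return `TRUE` if all sites in the band are occupied by one lineage.
#' @export
is_monoclonal <- function(state, band = state_geometry(state)$lgr5_rows) {
  rows <- band_rows(band) + 1L
  labs <- unclass(state)[rows, , drop = FALSE]
  if (any(labs < 0L)) return(FALSE)
  length(unique(as.integer(labs))) == 1L
}

#' Ablate a row band
#'
#' Empties all sites in `rows` (diphtheria-toxin-style targeted ablation of
#' the Lgr5+ zone) and switches the state to ablation mode, in which
#' relocation into vacancies and division into adjacent vacancies (without
#' push-up) refill the crypt. The mode reverts to homeostasis automatically
#' once the lattice is full again.
#'
#' @param state A homeostatic or ablated `crypt_state`.
#' @param rows Inclusive row band to empty, default the Lgr5+ zone.
#' @return The ablated `crypt_state`.
#' @examples
#' st <- ablate(build_homeostatic_state(), c(0, 3))
#' attr(st, "mode")
#' @export
ablate <- function(state, rows = state_geometry(state)$lgr5_rows) {
  g <- state_geometry(state)
  rows <- as.integer(rows)
  if (length(rows) != 2L || rows[1] > rows[2] || rows[1] < 0L || rows[2] >= g$n_rows)
    abort("`rows` must be an inclusive band inside the lattice", class = "cryptdrift_config_error")
  occ <- unclass(state)
  occ[band_rows(rows) + 1L, ] <- -1L
  new_crypt_state(occ, g, time = attr(state, "time"))
}

#' Lowest occupied row of a state
#'
#' @param state A `crypt_state`.
#' @return 0-based index of the lowest row containing at least one cell
#'   (`NA` if the lattice is empty).
#' @export
lowest_occupied_row <- function(state) {
  occ_rows <- which(apply(unclass(state) >= 0L, 1L, any))
  if (!length(occ_rows)) return(NA_integer_)
  occ_rows[1] - 1L
}
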