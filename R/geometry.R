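#' Crypt lattice geometry
#'
#' Defines the cylindrical lattice on which crypt dynamics are simulated:
#' `n_rows` rows of `cells_per_row` cells each, with row 0 at the crypt base
#' and cyclic column arithmetic (the cylinder). Row bands single out the
#' Lgr5+ zone and its centre/border sub-compartments; all bands are inclusive
#' integer ranges given as `c(first_row, last_row)`.
#'
#' Defaults follow the measured crypt organisation: 5 cells per row, Lgr5+
#' zone spanning rows 0-3 with centre rows 0-1 and border rows 2-3, and a
#' simulated height of 8 rows (twice the Lgr5+ zone) so that displaced clones
#' can transiently re-enter the niche before exiting past the top.
#'
#' @param n_rows Number of simulated rows (row 0 = crypt base).
#' @param cells_per_row Number of cells in each row (N_g); at least 2.
#' @param lgr5_rows Inclusive row band of the Lgr5+ zone.
#' @param centre_rows Inclusive row band of the centre compartment.
#' @param border_rows Inclusive row band of the border compartment.
#'
#' @return A `crypt_geometry` object (a named list).
#' @examples
#' geom <- crypt_geometry()
#' geom$cells_per_row
#' @export
crypt_geometry <- function(n_rows = 8L, cells_per_row = 5L,
                           lgr5_rows = c(0L, 3L),
                           centre_rows = c(0L, 1L),
                           border_rows = c(2L, 3L)) {
  n_rows <- as.integer(n_rows)
  cells_per_row <- as.integer(cells_per_row)
  band <- function(x, nm) {
    x <- as.integer(x)
    if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < 0L)
      abort(sprintf("`%s` must be an inclusive row band c(first, last) with 0 <= first <= last", nm),
            class = "cryptdrift_config_error")
    x
  }
  lgr5_rows <- band(lgr5_rows, "lgr5_rows")
  centre_rows <- band(centre_rows, "centre_rows")
  border_rows <- band(border_rows, "border_rows")
  if (is.na(cells_per_row) || cells_per_row < 2L)
    abort("`cells_per_row` must be at least 2", class = "cryptdrift_config_error")
  if (is.na(n_rows) || n_rows <= lgr5_rows[2])
    abort("`n_rows` must exceed the top row of `lgr5_rows`", class = "cryptdrift_config_error")
  cb <- c(seq.int(centre_rows[1], centre_rows[2]), seq.int(border_rows[1], border_rows[2]))
  if (anyDuplicated(cb) || !setequal(cb, seq.int(lgr5_rows[1], lgr5_rows[2])))
    abort("`centre_rows` and `border_rows` must be disjoint and partition `lgr5_rows`",
          class = "cryptdrift_config_error")
  structure(
    list(n_rows = n_rows, cells_per_row = cells_per_row,
         lgr5_rows = lgr5_rows, centre_rows = centre_rows, border_rows = border_rows),
    class = "crypt_geometry")
}

#' @export
print.crypt_geometry <- function(x, ...) {
  cat(sprintf("<crypt_geometry> %d rows x %d cells/row (cylinder)\n", x$n_rows, x$cells_per_row))
  cat(sprintf("  Lgr5+ zone rows %d-%d (centre %d-%d, border %d-%d)\n",
              x$lgr5_rows[1], x$lgr5_rows[2], x$centre_rows[1], x$centre_rows[2],
              x$border_rows[1], x$border_rows[2]))
  invisible(x)
}

band_rows <- function(band) seq.int(band[1], band[2])

#' Kinetic parameters of the stochastic conveyor belt
#'
#' The model has two per-cell rates: the division rate `k_d` (divisions per
#' cell per day, driving anterograde displacement towards the crypt mouth) and
#' the relocation rate `k_r` (neighbour exchanges per cell per day, the source
#' of retrograde movement). Their dimensionless ratio k_r/k_d is the single
#' parameter controlling long-term clonal fate; either `k_r` or `ratio` may be
#' given.
#'
#' @param k_d Division rate per cell per day (> 0). Default 1.4/day.
#' @param k_r Relocation rate per cell per day (>= 0).
#' @param ratio Alternative to `k_r`: the dimensionless ratio k_r/k_d.
#'
#' @return A `kinetic_params` object with fields `k_d`, `k_r` and `ratio`.
#' @examples
#' kinetic_params(k_d = 1.4, ratio = 2)
#' @export
kinetic_params <- function(k_d = 1.4, k_r = NULL, ratio = NULL) {
  if (is.null(k_r) + is.null(ratio) != 1L)
    abort("give exactly one of `k_r` or `ratio`", class = "cryptdrift_config_error")
  if (!is.numeric(k_d) || length(k_d) != 1L || is.na(k_d) || k_d <= 0)
    abort("`k_d` must be a single positive rate (per day)", class = "cryptdrift_config_error")
  if (is.null(k_r)) {
    if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0)
      abort("`ratio` must be a single non-negative number", class = "cryptdrift_config_error")
    k_r <- ratio * k_d
  }
  if (!is.numeric(k_r) || length(k_r) != 1L || is.na(k_r) || k_r < 0)
    abort("`k_r` must be a single non-negative rate (per day)", class = "cryptdrift_config_error")
  structure(list(k_d = k_d, k_r = k_r, ratio = k_r / k_d), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("<kinetic_params>%s k_d = %g/day, k_r = %g/day (k_r/k_d = %g)\n",
              if (is.null(cond)) "" else paste0(" [", cond, "]"), x$k_d, x$k_r, x$ratio))
  invisible(x)
}

#' Experimental condition presets
#'
#' Best-fit kinetic parameters for the three fitted conditions: small
#' intestine (`"SI"`, k_r/k_d = 2), large intestine (`"LI"`, k_r/k_d = 0.25)
#' and porcupine-inhibitor-treated small intestine (`"SI_LGK974"`,
#' k_r/k_d = 0.4). All share k_d = 1.4/day; Wnt inhibition enters only
#' through the reduced relocation rate.
#'
#' @param condition One of `"SI"`, `"LI"`, `"SI_LGK974"`.
#' @param k_d Division rate override (per day).
#'
#' @return A [kinetic_params()] object tagged with the condition name.
#' @examples
#' crypt_preset("SI")
#' @export
crypt_preset <- function(condition = c("SI", "LI", "SI_LGK974"), k_d = 1.4) {
  condition <- match.arg(condition)
  ratio <- c(SI = 2, LI = 0.25, SI_LGK974 = 0.4)[[condition]]
  p <- kinetic_params(k_d = k_d, ratio = ratio)
  attr(p, "condition") <- condition
  p
}
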