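# shared fixtures built in code

default_geom <- crypt_geometry()

# retention fraction by starting row from a batch of traced clones
retention_by_row <- function(params, n_per_row, t = 56, rows = 0:3,
                             geometry = default_geom) {
  obs <- run_lineage_tracing(params, geometry, start_rows = rows,
                             n_clones_per_row = n_per_row, record_times = t)
  cts <- retention_counts(obs, t)
  stats::setNames(cts$n_retained / cts$n_clones, cts$start_row)
}

# where did the duplicated / moved label go? returns c(drow, dcol offsets)
displacement_of_new_label <- function(before, after, site) {
  lab <- unclass(before)[site[1] + 1L, site[2] + 1L]
  hits <- which(unclass(after) == lab, arr.ind = TRUE) - 1L
  hits <- hits[!(hits[, 1] == site[1] & hits[, 2] == site[2]), , drop = FALSE]
  hits
}
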