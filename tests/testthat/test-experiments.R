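test_that("lineage tracing scores retention, compartments and clone size", {
  set.seed(41)
  obs <- run_lineage_tracing(crypt_preset("SI"), start_rows = c(0, 3),
                             n_clones_per_row = 40, record_times = c(2, 56))
  expect_s3_class(obs, "clone_observations")
  expect_equal(nrow(obs), 160L)
  expect_true(all(obs$retained == (obs$in_centre | obs$in_border)))
  expect_true(all(vapply(obs$cells_by_row, sum, integer(1)) == obs$n_cells))
  # clones start as the single induced cell
  first <- dplyr::filter(obs, .data$time_days == 2)
  expect_true(all(first$n_cells >= 0))
  expect_error(run_lineage_tracing(crypt_preset("SI"), start_rows = 99),
               class = "cryptdrift_config_error")
  expect_equal(nrow(run_lineage_tracing(crypt_preset("SI"), n_clones_per_row = 0)), 0L)
})

test_that("compartment summary partitions clones into centre / border-only / lost", {
  obs <- tibble::tibble(
    clone_id = 1:3, condition = "custom", start_row = c(0L, 2L, 3L),
    time_days = 3, n_cells = c(2L, 1L, 0L),
    retained = c(TRUE, TRUE, FALSE),
    in_centre = c(TRUE, FALSE, FALSE),
    in_border = c(TRUE, TRUE, FALSE),
    fragmented = FALSE, cells_by_row = list(0, 0, 0))
  s <- compartment_transition_summary(obs)
  expect_equal(sum(s$n_clones), 3L)
  tot <- s$p_centre + s$p_border_only + s$p_lost
  expect_true(all(abs(tot - 1) < 1e-12))
  centre_row <- dplyr::filter(s, .data$start_compartment == "centre")
  expect_equal(centre_row$p_centre, 1)
  border <- dplyr::filter(s, .data$start_compartment == "border")
  expect_equal(sum(border$n_clones), 2L)
  expect_error(compartment_transition_summary(obs[0, ]), class = "cryptdrift_empty_error")
})

test_that("fragmentation is a pure function of row occupancy", {
  g <- default_geom
  occ <- matrix(0L, g$n_rows, g$cells_per_row)
  occ[1, 1] <- 1L; occ[2, 3] <- 1L
  st <- cryptdrift:::new_crypt_state(occ, g)
  expect_false(is_fragmented(st, 1L)) # rows {0,1}: contiguous
  occ2 <- occ; occ2[2, 3] <- 0L; occ2[3, 3] <- 1L
  st2 <- cryptdrift:::new_crypt_state(occ2, g)
  expect_true(is_fragmented(st2, 1L)) # rows {0,2}, nothing in row 1
  expect_identical(is_fragmented(st2, 1L), is_fragmented(st2, 1L))
  occ3 <- matrix(0L, g$n_rows, g$cells_per_row); occ3[5, 2] <- 1L
  expect_false(is_fragmented(cryptdrift:::new_crypt_state(occ3, g), 1L)) # single cell
  expect_error(is_fragmented(st, 7L), class = "cryptdrift_logic_error")
})

test_that("fragmentation is likelier with fast relocation than with none", {
  set.seed(42)
  si <- run_fragmentation_assay(crypt_preset("SI"), n_clones = 1200, t = 7)
  li <- run_fragmentation_assay(crypt_preset("LI"), n_clones = 1200, t = 7)
  none <- run_fragmentation_assay(kinetic_params(k_d = 1.4, k_r = 0),
                                  n_clones = 1200, t = 7)
  expect_gt(si$probability, li$probability)
  expect_gt(si$probability, none$probability)
  expect_error(run_fragmentation_assay(crypt_preset("SI"), n_clones = 0),
               class = "cryptdrift_config_error")
  expect_error(run_fragmentation_assay(crypt_preset("SI"), t = 0),
               class = "cryptdrift_config_error")
})

test_that("monoclonal drift starts polyclonal and the LI converts faster", {
  set.seed(43)
  si <- run_monoclonal_drift(crypt_preset("SI"), n_crypts = 60, record_times = c(1e-9, 3, 7, 14))
  li <- run_monoclonal_drift(crypt_preset("LI"), n_crypts = 60, record_times = c(1e-9, 3, 7, 14))
  expect_equal(si$fraction_monoclonal[1], 0)
  expect_true(all(si$fraction_monoclonal >= 0 & si$fraction_monoclonal <= 1))
  mid <- si$time_days %in% c(3, 7)
  expect_true(all(li$fraction_monoclonal[mid] > si$fraction_monoclonal[mid]))
})

test_that("every crypt eventually becomes monoclonal (drift is fastest with no relocation)", {
  set.seed(44)
  out <- run_monoclonal_drift(kinetic_params(k_d = 1.4, k_r = 0),
                              n_crypts = 30, record_times = 60)
  expect_equal(out$fraction_monoclonal, 1)
})

test_that("ablation empties the band and recovery refills it from above", {
  st <- build_homeostatic_state(default_geom, "single-label")
  ab <- ablate(st, c(0, 3))
  expect_equal(attr(ab, "mode"), "ablation")
  expect_equal(sum(is.na(as_tibble(ab)$label)), 20L)
  expect_equal(lowest_occupied_row(ab), 4L)
  expect_equal(unclass(ablate(ab, c(0, 3)))[, ], unclass(ab)[, ]) # idempotent
  expect_error(ablate(st, c(0, 99)), class = "cryptdrift_config_error")

  set.seed(45)
  si <- run_ablation_recovery(crypt_preset("SI"), n_crypts = 120,
                              record_times = c(0.01, 1, 2, 4, 7, 15))
  expect_true(all(diff(si$summary$mean_lowest_row) <= 0)) # monotone recovery
  expect_lt(abs(si$summary$mean_lowest_row[1] - 4), 0.2)  # just above the band at t ~ 0+
  li <- run_ablation_recovery(crypt_preset("LI"), n_crypts = 120,
                              record_times = c(0.01, 1, 2, 4, 7, 15))
  # stronger retrograde movement refills the niche faster
  expect_lt(mean(si$summary$mean_lowest_row), mean(li$summary$mean_lowest_row))
  # simulation leaves ablation mode once the lattice refills: labels conserved
  expect_true(all(si$per_crypt$lowest_row >= 0 & si$per_crypt$lowest_row <= 7))
})

test_that("long-term retention falls with starting row, more steeply in the LI", {
  set.seed(46)
  si <- retention_by_row(crypt_preset("SI"), n_per_row = 800)
  li <- retention_by_row(crypt_preset("LI"), n_per_row = 800)
  expect_true(all(diff(si) <= 0))
  expect_true(all(diff(li) <= 0))
  # normalised profiles: LI below SI at every row > 0
  expect_true(all((li / li[1])[2:3] < (si / si[1])[2:3]))
})
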