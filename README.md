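# cryptdrift

Stochastic conveyor-belt dynamics of intestinal crypt stem cells: an exact
lattice simulator of neutral clonal competition with division-driven upward
displacement and stochastic cell relocation, plus the closed-form retention
theory, in-silico lineage-tracing / monoclonality / fragmentation / ablation
experiments, and likelihood-based inference of the relocation-to-division
ratio from clone-tracing tables.

## The problem

Intestinal crypts renew from stem cells at their base. Division pressure
pushes cells up and out of the crypt like a conveyor belt, so naively only
the bottom row of cells should ever found long-lived lineages. Live imaging
shows otherwise: cells also relocate stochastically, including *retrograde*
(base-ward) movements, and cells starting several rows up can fall back into
the niche and win the competition. `cryptdrift` is for quantitative
biologists who want to simulate this competition, design virtual
lineage-tracing experiments on it, and infer its governing parameter from
clone-retention data.

## The model

Crypts are cylindrical lattices (`n_rows` x `cells_per_row`, row 0 = base,
cyclic columns; rows 0–3 are the Lgr5⁺ zone with centre rows 0–1 and border
rows 2–3). Two per-cell Poisson processes drive the dynamics:

- **division** at rate *k*<sub>d</sub> (default 1.4/day): the label is
  duplicated, the daughter is inserted at a uniformly chosen neighbour
  (left, right or above), the insertion column shifts up one row and the
  topmost cell exits — anterograde, conveyor-belt transfer;
- **relocation** at rate *k*<sub>r</sub>: the cell swaps with a uniformly
  chosen lattice neighbour — downward swaps are retrograde movements.

Long-term clone retention depends only on the dimensionless ratio
*k*<sub>r</sub>/*k*<sub>d</sub>, through a Gaussian law for the probability
that a clone induced at row *x* holds the niche:

P(x) ∝ exp( −x² / 2σ² ),  σ² = *k*<sub>r</sub>/*k*<sub>d</sub>,

which yields an effective stem-cell number
N<sub>s</sub> ≈ N<sub>g</sub> (1 + 2√(*k*<sub>r</sub>/*k*<sub>d</sub>)) and
an effective-row count (rows with ≥5% normalised retention). Presets carry
the fitted conditions: `"SI"` (small intestine, ratio 2), `"LI"` (large
intestine, ratio 0.25), `"SI_LGK974"` (Wnt-secretion inhibited, ratio 0.4).

## Worked example

```r
library(cryptdrift)
set.seed(42)

effective_stem_cell_number(5, 2)
#> <stem_cell_estimate> N_s = 19.14 (~19) at N_g = 5, k_r/k_d = 2; 4 effective row(s) above 5% retention
effective_stem_cell_number(5, 0.25)
#> <stem_cell_estimate> N_s = 10.00 (~10) at N_g = 5, k_r/k_d = 0.25; 2 effective row(s) above 5% retention

# simulate an 8-week lineage-tracing experiment in the large intestine and
# re-infer the generating ratio from the retention-by-starting-row table
obs <- run_lineage_tracing(crypt_preset("LI"), n_clones_per_row = 2000,
                           record_times = c(2, 56))
fit <- fit_ratio_longterm(retention_counts(obs, 56), n_boot = 1000)
fit
#> <ratio_fit> k_r/k_d = 0.287 (95% CI 0.238-0.339, 1000 bootstrap resamples)
#>   p0 = 0.176, N_s = 10.4 at N_g = 5, -logLik = 13.14

# monoclonal drift from all-distinct labelling, scored over the Lgr5+ zone
run_monoclonal_drift(crypt_preset("SI"), n_crypts = 100,
                     record_times = c(7, 14, 42))
#> # A tibble: 3 x 4
#>   condition time_days fraction_monoclonal n_crypts
#>   <chr>         <dbl>               <dbl>    <dbl>
#> 1 SI                7                0.38      100
#> 2 SI               14                0.81      100
#> 3 SI               42                1         100
```

The first two calls evaluate the closed-form theory: ~19 effective stem
cells per small-intestinal crypt versus ~10 (the first two rows) per
large-intestinal crypt. The fit recovers the generating ratio 0.25 within
its bootstrap interval from 8,000 simulated clones; `p0` is the absolute
8-week survival of a base-row clone. The monoclonality series shows the
fraction of crypts taken over by a single lineage.

Other entry points: `simulate_crypt()` (raw trajectories and event logs),
`compartment_transition_summary()`, `run_fragmentation_assay()`,
`run_ablation_recovery()`, `fit_kd_shortterm()`, `generate_study()`
(a full synthetic study bundle), `read_run_config()` /
`write_observations()` for YAML configs and provenance-stamped CSV tables,
and `autoplot()` methods for fits, monoclonality series and ablation
trajectories. `reproduce_analyses(seed)` reruns every headline analysis in
one call.

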