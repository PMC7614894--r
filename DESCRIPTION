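Package: cryptdrift
Title: Stochastic Conveyor-Belt Dynamics of Intestinal Crypt Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates neutral clonal competition in intestinal crypts as a
    stochastic conveyor belt: cells on a cylindrical lattice divide (rate k_d,
    pushing neighbours towards the crypt mouth) and relocate by neighbour
    exchange (rate k_r), so that retrograde movement back towards the niche
    rescues lineages that would otherwise be swept away. Provides an exact
    event-driven (Gillespie) lattice simulator, closed-form Gaussian
    clone-retention theory and effective stem-cell-number estimators, in-silico
    lineage tracing, monoclonal drift, clone fragmentation and ablation-recovery
    experiments, maximum-likelihood inference of the dimensionless ratio
    k_r/k_d from clone-tracing tables with bootstrap confidence intervals, and
    a synthetic-study generator emulating intravital lineage-tracing designs in
    the small and large intestine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    readr,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
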