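Package: elembudget
Title: Elemental Scope-for-Growth Budgets for Suspension-Feeding Bivalves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes carbon and nitrogen scope-for-growth budgets for
    suspension-feeding bivalves from standard physiological measurements
    (clearance rate, Conover absorption efficiency, oxygen consumption,
    ammonia excretion) combined with gravimetric and elemental
    characterization of the food suspension and feces.  Derives C:N ratios
    along the successive budget components (ingested, egested, absorbed,
    metabolic, retained), partitions the stoichiometric adjustment between
    pre- and post-absorptive processes, fits exponential decays of element
    absorption efficiency against ingestion rate, and runs the factorial
    ANOVA layouts used in feeding-physiology experiments.  Includes a
    synthetic-experiment generator reproducing the group-level structure of
    a juvenile carpet-shell clam (Ruditapes decussatus) feeding study, so
    the full pipeline is testable without access to raw replicate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
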