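Package: mrgxe
Title: Gene-Environment Interaction Mendelian Randomization with
    Metabolite Polygenic Scores
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: One-sample Mendelian randomization in which a polygenic score
    instruments a metabolite exposure and a polygenic-score-by-treatment
    product term identifies treatment-dependent genetic effects on a
    glycaemic outcome.  Implements the full individual-level workflow:
    variant quality control (minor-allele frequency, Hardy-Weinberg,
    call rate), linkage-disequilibrium pruning and genotype principal
    components, per-metabolite association scans, greedy LD clumping,
    pleiotropy and blocklist screening, polygenic-score construction,
    instrument-strength and collider diagnostics, a two-stage
    least-squares estimator with Wald inference and effect-pattern
    classification, leave-one-out sensitivity analysis, and a
    synthetic-cohort generator with known truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
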