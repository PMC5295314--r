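Package: gemeta
Title: Genotype-Count Meta-Analysis with Gene-Environment Meta-Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Meta-analysis of case-control genotype count tables for tri-genotype
    loci (e.g., MTHFR C677T and A1298C), using genotype-versus-total risk ratios
    pooled under inverse-variance fixed-effect and DerSimonian-Laird random-effects
    models with Cochran's Q and I-squared heterogeneity statistics, Hardy-Weinberg
    equilibrium checks, Egger regression and funnel-plot exports, subgroup and
    leave-one-out sensitivity analyses, and a "meta-prediction" stage relating
    study-level genotype percentages and risk ratios to ordinal air-pollution
    mortality strata via single-split partition trees scored by AICc, Tukey-Kramer
    pairwise comparisons, trend-curve fits and heat-map matrices. Includes a
    seeded synthetic study-table generator and a deterministic 44-group fixture
    for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
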