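Package: dssa
Title: Differential Strain Sensitivity Analysis for Pooled Fitness Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide functional profiling of pooled yeast
    deletion collections grown competitively under a stress condition.
    Simulates pooled competitive growth and barcode-array hybridization
    signals with known ground truth; calls condition-sensitive and
    condition-resistant strains by differential strain sensitivity
    analysis (per-pair outlier q-values, same-sign exact binomial
    consistency test, genome-wide q-value correction); runs
    hypergeometric category over-representation with Bonferroni
    correction; searches interaction networks for high-scoring active
    sub-networks with Monte-Carlo size calibration; and quantifies
    confirmation assays (flow-cytometry competition gating and ratios,
    growth-curve AUC, culture generation arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    fgsea,
    pracma
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
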