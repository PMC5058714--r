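Package: oncomodules
Title: Discovery and Evidence Scoring of Oncomodules Dysregulated by
    Chromatin Regulator Driver Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates paired somatic-mutation and expression data from a
    tumor cohort to find gene modules ("oncomodules") whose collective
    expression shifts with driver mutations of chromatin regulatory factors
    (CRFs).  Provides the full discovery pipeline: per-sample CRF-to-driver
    mutation enrichment index, variance filtering and rank-sum differential
    expression between mutated and CRF-clean samples with adaptive FDR
    thresholds, hypergeometric gene-set enrichment with a raw-p add-back
    rule, sample-level enrichment Z-scores (analytic finite-population and
    resampling modes), a seven-layer evidence scorecard, and a permutation
    test for mutual exclusivity of alterations.  A synthetic cohort,
    cell-line panel, and knock-down signature generator with a ground-truth
    ledger supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
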