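Package: milletgp
Title: Genomic Prediction for Single-Cross Pearl Millet Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in a three-line (CMS) hybrid
    breeding program: genotype calling from allele read depths with
    depth/frequency thresholds, per-marker quality statistics and
    filtering, projection of F1 hybrid genotypes from inbred parents,
    REML variance components and BLUPs for multi-location alpha-lattice
    trials with broad-sense heritability and mid-parent heterosis, and
    RR-BLUP genomic prediction under four training schemes (inbred-only,
    hybrid-only, and combined training with or without per-population
    centering) with repeated fivefold cross-validation, marker
    subsampling, hold-out-parent validation, exhaustive prediction of all
    possible crosses, and a yield/flowering trade-off frontier. Includes
    a seeded synthetic-data generator (founder pools, cross plans,
    additive+dominance trait architectures, alpha-lattice field books)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
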