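Package: cnvrevert
Title: Wright-Fisher Modeling and Simulation-Based Inference of CNV Reversion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the stability of adaptive copy-number
    amplifications (CNVs) after the selective pressure that created them is
    removed. Implements a discrete-generation Wright-Fisher model of CNV
    reversion with selection, mutation and drift for one or two loci;
    amortized neural posterior estimation of reversion rate, selection
    coefficient and initial revertant frequency from noisy CNV-frequency
    trajectories, using a conditional masked autoregressive flow trained on
    model simulations, with collective posteriors across replicate
    populations, simulation-based calibration and posterior predictive
    checks; the fixed-intercept log-ratio regression used in pairwise
    competitive fitness assays; predicted fitness-cost scoring of segmental
    amplifications and aneuploidies from per-gene duplication-cost tables;
    flow-cytometry gate construction and copy-number classification;
    CNV-loss phase statistics; ploidy-normalized copy-number tracks from
    sequencing depth; and seeded synthetic-data generators for every input
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
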