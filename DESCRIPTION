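Package: ntracts
Title: Detection, Dating and Testing of Neanderthal Ancestry Tracts in Ancient Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing archaic introgression in low-coverage ancient
    genomes. Implements ancient-DNA authentication and quality control
    (terminal deamination filtering, pseudo-haploid calling with damage
    masking, contamination, genetic sex and individual-identity estimation),
    f-statistics (f2, f3, f4, D) with weighted block jackknife standard
    errors, direct f4-ratio estimation of archaic ancestry proportions,
    admixture-graph fitting with residual diagnostics, a diploid hidden
    Markov model that detects Neanderthal ancestry segments in genetic-map
    coordinates, maximum-likelihood dating of a recent Neanderthal ancestor
    from long segment lengths, and permutation tests of segment overlap with
    introgression deserts. A synthetic-data generator reproduces the
    statistical structure of capture-based ancient-DNA data sets
    (graph-drifted allele frequencies, pedigree-recombination ancestry
    tracts, Poisson coverage, terminal C-to-T deamination, present-day
    contamination and sequencing error) for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    igraph,
    pracma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
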