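Package: mosaicsim
Title: Mosaic Genome Simulation and Local Ancestry Benchmarking for
    Plant-Like Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates chromosome-wide genotyping data for admixed,
    crop-like populations: founder haplotypes are drawn from a star-shaped
    pure-drift coalescent of S differentiated source populations, then
    reproduced forward in time under mixtures of within- and
    across-population random mating, selfing and vegetative (clonal)
    propagation, with exact bookkeeping of true local-ancestry tracts.
    Provides scenario presets, Weir-Cockerham FST, heterozygosity and
    ancestry-block summary statistics, VCF/plink/truth-table export, and
    an accuracy metric (one minus half the L1 distance between true and
    inferred ancestry dosages) to score external local-ancestry inference
    output against the simulated truth, including a random-inference
    baseline and missing-source masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
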