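Package: macall
Title: Mutation Calling for Mutation Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls accumulated clonal and candidate subclonal mutations from
    matched ancestor (t0) and descendant (outgrowth) sequencing samples.
    Operates on strand-specific allele-count tables and per-position depth
    tracks, building per-sample empirical models of depth, strand bias, and
    PCR slippage indel error in simple repeats.  Mutations are identified by
    statistical comparison of ancestor and descendant read counts with
    family-wise error control, genotypes are assigned by score minimisation
    over enumerated clonal/subclonal models with error-corrected expected
    allelic frequencies, and mutation identities are inferred by parsimonious
    event-path enumeration with explicit ambiguity grouping.  Also includes
    mutation-rate utilities, a false-negative model for indels in long
    repeat tracts, a Monte Carlo simulator of indel accumulation in
    homopolymers, and a fully seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
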