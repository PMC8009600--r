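Package: malines
Title: Mutation-Accumulation Line Analysis: Mutation Rates, Spectra and
    Effective Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of bacterial mutation-accumulation (MA) experiments
    from per-site read-count tables to population-genetic summaries.
    Implements consensus-based mutation calling across MA lines with
    line-level quality control and cross-contamination screening;
    mutation-rate estimation per site per cell division with exact
    (Garwood) Poisson confidence intervals; conditional per-type mutation
    spectra, A/T mutation bias, transition/transversion ratio and the
    equilibrium A+T genome content expected under mutation pressure alone;
    four-fold degenerate site identification from a genome annotation,
    pairwise nucleotide diversity across strain alignments and effective
    population size as theta over twice the mutation rate. A seeded
    simulator generates annotated genomes, planted mutations, pileups with
    sequencing error, colony-count tables and diverged strain alignments so
    that every stage can be tested against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
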