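Package: ekmersim
Title: Empirical Context-Dependent Simulation of Long Noisy Sequencing Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learn-and-simulate toolkit for long single-molecule sequencing
    reads. A non-parametric, sequencing-context-dependent error model is
    trained from read-versus-reference alignments (SAM/BAM), keyed by
    extended-k-mer contexts: a central homopolymer run of any length plus
    fixed-width flanking bases. The fitted model records per-context event
    frequencies (match, insertion, deletion, substitution) together with
    sampled basecall emissions and per-base quality features, and is used to
    simulate multi-pass reads from arbitrary FASTA targets with strand
    alternation, hairpin adapters, custom error rates, position-dependent
    error scaling, and exhaustive ground truth. Includes error-profile
    analytics (per-context accuracy histograms, homopolymer length-transition
    distributions), FASTQ/tagged-BAM/BED output writers, and a fully
    parameterized synthetic fixture generator used as the statistical oracle
    for the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
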