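Package: malrsucc
Title: Reconstruction of LTR Retrotransposon Succession Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the succession history of LTR
    retrotransposon families from standard repeat-annotation resources.
    Parses RepeatMasker .out annotations and UCSC chain files, dates
    insertions relative to species splits by orthologous presence/absence
    (liftOver-style interval lifting with flank-alignment quality control),
    detects transposition-in-transposition (TinT) events from annotation
    geometry and infers relative family activity periods on pseudo-time by
    maximum likelihood, builds neighbor-joining trees of family consensus
    sequences from free-end-gap pairwise alignments under the Jukes-Cantor
    model, and genotypes element copies for named consensus-anchored
    structural variants to order the structural changes between successive
    families under LTR replication logic. A synthetic genome-evolution
    simulator with machine-readable truth tables makes every pipeline stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    Biostrings,
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer,
    GenomicRanges,
    IRanges,
    optparse,
    withr
Config/testthat/edition: 3
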