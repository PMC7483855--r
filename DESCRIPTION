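Package: nanoasm
Title: Long-Read Assembly and Polishing in Run-Length Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale de novo assembler and polisher for noisy long
    (nanopore-like) reads. Reads are run-length encoded to suppress
    homopolymer length errors, summarised as sequences of marker k-mers,
    overlapped with a low-hash (threshold MinHash) scheme, aligned in
    marker space by banded sparse dynamic programming, and merged into a
    marker graph that is simplified (approximate transitive reduction,
    leaf pruning, bubble and superbubble removal) and condensed into an
    assembly graph from which run-length consensus sequence is assembled.
    A polishing stage refines draft assemblies using pair-HMM alignment
    posteriors summarised in a weighted partial-order graph, local
    haplotype proposal with likelihood evaluation, and Bayesian decoding
    of homopolymer run lengths from a trained confusion-matrix model.
    Includes a nanopore-like read simulator with truth tracking for
    validation, FASTA/FASTQ/SAM/GFA input and output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
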