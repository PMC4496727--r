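Package: isoscan
Title: K-Best Gene Structure Prediction with RNA-Seq Junction Validation
    and a Coding-Transcript Census
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An alternative-isoform discovery kit built around a
    generalized (explicit-duration) hidden Markov model of gene
    structure.  A k-best Viterbi decoder returns the top-N
    complete-ORF gene structures per genomic region rather than the
    single optimum, so that sub-optimal paths yield candidate splice
    isoforms.  Candidates are validated against RNA-seq read
    alignments in mature-transcript space using a two-sided splice
    junction coverage rule and tiered into high/medium/low confidence
    classes via a novel-internal-junction filter.  The kit also
    classifies alternative-splicing events between isoforms of a gene
    into seven canonical categories, filters proteomic peptide
    identifications down to novel-protein calls, and implements a
    closed-form estimator of the total number of coding transcripts
    from known-set sensitivity.  Deterministic simulators for genomes,
    junction-spanning reads and peptide tables make every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
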