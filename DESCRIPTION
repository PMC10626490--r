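Package: stemwax
Title: Cell-Type Coexpression Gene Regulatory Networks and Cuticular Wax
    Morphometrics for Plant Stems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor-centred gene regulatory networks from
    cell-type-resolved RNA-seq of plant stems, as used to study epidermal
    cuticular wax biosynthesis. Implements gene-level aggregation of
    transcript abundances, TPM expression thresholding, trimmed-mean-of-M-values
    (TMM) normalization, a negative-binomial exact test for
    epidermis-versus-other differential expression, all-pairs Pearson
    correlation with the Mutual Rank statistic, strand-aware 1-kb promoter
    extraction with log-odds position-weight-matrix scanning and Fisher-test
    cis-regulatory-element enrichment, and assembly, export and scoring of the
    resulting TF-target network. A synthetic-data module generates cell-type
    count matrices, promoters and motifs with planted ground truth so the whole
    pipeline is verifiable offline. Companion morphometric routines compute
    internode surface area from a two-truncated-cone model, cuticular wax load
    per unit area, and wax-class composition summaries with group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
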