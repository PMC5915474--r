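Package: bifscan
Title: Census of Bifunctional Gene Loci from Transcript Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions gene loci by their RefSeq isoform content into
    coding-only, non-coding-only and bifunctional classes, quantifies whether
    short expression-array probes can distinguish coding from non-coding
    isoforms of the same locus by exact sequence matching against spliced
    transcripts, compares expression of exclusively-coding versus
    exclusively-non-coding probe groups with a rank-sum test, and tests
    gene lists for gene-set overrepresentation with a hypergeometric model.
    Ships a synthetic-data generator (genome, annotation, probe table,
    expression matrix, gene-set library) with full ground truth so every
    pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
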