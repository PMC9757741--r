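Package: mitecoopt
Title: Detection of Transposon-Derived Germline Promoters in Nematode Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying the co-option of miniature
    inverted repeat transposable elements (MITEs) as germline-specific
    promoters. Provides differential-accessibility classification of ATAC-seq
    peaks between wild-type and germline-less animals, promoter annotation of
    accessible sites from stranded nuclear RNA-seq coverage (outron linking
    plus a directional signal test), position weight matrix scanning with
    exact p-values, annotation of paired motif occurrences into arrangement
    classes, permutation-based repeat enrichment with gene-body exclusion,
    direct-target calling from differential expression and ChIP peaks, and
    cross-species conservation classification of co-opted promoters over 1:1
    orthologs. Includes a deterministic synthetic-genome generator that plants
    MITE-like elements with full ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
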