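Package: scpfilter
Title: Filtering Somatic Variant Artifacts from Enzymatically Fragmented
    Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and removes artifactual somatic SNVs/indels introduced by
    endonuclease-based DNA fragmentation during hybridization-capture library
    preparation. Such artifacts sit at the centers of palindromic reference
    contexts (SNV-centered palindromes), cluster 10-15 bases from read ends,
    and ride on heavily soft-clipped reads. The package extracts read-level
    evidence from BAM files (in-read variant offsets via CIGAR walking, a
    two-sample Kolmogorov-Smirnov positional-bias test, the soft-clipped read
    ratio), applies a two-stage filter (cohort recurrence with whitelist
    rescue, then a logistic noise classifier thresholded to maximize
    sensitivity plus specificity), and demonstrates noise cancellation by
    constrained refitting of 96-class trinucleotide mutational signatures.
    A bundled simulator generates references with embedded hairpin
    palindromes, aligned reads with implanted artifact and genuine variants,
    cohort call tables and signature-mixture spectra, so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    methods,
    quadprog,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
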