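Package: tecre
Title: Transposable-Element-Derived Cis-Regulatory Element Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to discover and characterize transposable-element (TE)
    derived regulatory elements at tandem gene arrays. Implements repeat-family
    enrichment testing of regulatory peak sets with transcription-factor
    co-occupancy, clustering, and promoter/enhancer activity classification;
    TE-to-gene-3'-end proximity analysis; polyadenylation cis-element scanning
    with instance-to-consensus coordinate lifting and a paired co-occurrence
    test; isoform grouping by terminal-exon TE overlap; classical hydropathy
    profiling for isoform topology comparison; combined transcription-factor
    dosage correlation statistics; locus copy-number burden tests; and ungapped
    oligonucleotide specificity scoring with Karlin-Altschul bit conversion.
    Ships a seeded synthetic-data module that generates fixtures with the
    statistical structure each analysis stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
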