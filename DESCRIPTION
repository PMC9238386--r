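Package: crisptarget
Title: CRISPR Spacer Targeting Analysis of Prophages in Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing CRISPR-mediated targeting of prophages in
    multi-species bacterial communities. Implements repeat-seeded CRISPR array
    detection and spacer extraction, exact (zero-mismatch, full-length)
    spacer-to-protospacer matching with array self-match removal, prophage
    versus genome-backbone targeting-density statistics with per-kilobase
    Mann-Whitney testing and Holm-Sidak correction, percent-length-aligned
    dereplication and average-linkage clustering of mobile genetic elements,
    directed interspecies targeting networks, and CRISPR-based inference of
    prophage host species. Includes a synthetic community generator that
    plants prophages, CRISPR arrays and protospacers with full ground truth,
    so every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
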