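Package: cmcensus
Title: Construction and Validation of a Cancer miRNA Gene Census
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a census of cancer-related miRNA genes from multi-criterion
    evidence: rank-percentile scoring of miRNA-cancer association counts across
    three literature databases, direction-consistency assessment, and binary
    functional/genetic evidence flags. Provides leave-one-out and graded-score
    validation of the scoring criteria, oncogene/tumor-suppressor designation
    from direction consistency plus tumor-versus-normal differential-expression
    calls, top-validated target selection with reference-list overlap
    statistics, generic term overrepresentation with fold enrichment and
    Benjamini-Hochberg FDR, and a calibrated synthetic-data generator with
    known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
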