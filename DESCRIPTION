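Package: proteoMap
Title: Batch-Normalized Tumor Proteome Mapping with Proteogenomic and PTM
    Bookkeeping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a relative protein-abundance map from
    multi-batch label-free and isobaric (TMT) quantitative proteomics of
    tumor cohorts: peptide-to-protein roll-up (TOP3, reporter-ion summation),
    two-stage normalization (intra-sample median centering and inter-batch
    correction anchored on low-variability reference proteins), derivation of
    mutation-bearing tryptic peptides from driver-mutation panels with
    cleavage-gain/loss logic and peptide uniqueness checking, integration of
    the protein map with tumor transcriptomes (overlap, correlation, 1D
    rank-based annotation enrichment), phosphoproteome and kinome coverage
    analysis with motif enrichment, lysine-acetylation site occupancy from
    light/heavy intensity pairs, and NSAF plasma profiling with blood-origin
    classification. A seeded synthetic-data module emulates the statistical
    structure of such cohorts (log-normal abundances over ~6 orders of
    magnitude, abundance-dependent missingness, planted reference proteins,
    paired transcript counts, Beta-distributed acetylation occupancies) so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
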