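Package: rgescore
Title: Reverse Gene Expression Scoring for Signature-Based Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how strongly drug-induced transcriptional profiles reverse
    a disease gene-expression signature. Builds directed up/down disease
    signatures from differential-expression tables restricted to a landmark
    gene universe, computes a Kolmogorov-Smirnov-style Reverse Gene Expression
    Score (RGES) for each perturbation profile, normalizes scores across
    heterogeneous assay conditions (dose, treatment duration) toward a
    reference condition, weights by cell-line-to-tumour transcriptional
    similarity, and summarizes to one score per compound (sRGES). Also
    identifies individual signature genes specifically reversed by effective
    compounds via one-sided rank tests with leave-one-compound-out robustness
    filtering, and ships a synthetic-study generator with recorded ground
    truth for end-to-end validation. Includes a command-line interface and
    readers for delimited tables and GCT v1.3 text matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
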