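Package: anchorseek
Title: Anchor-Gene Correlation Screening Across Species in Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "anchorseek", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to discover genes whose single-cell expression tracks a
    chosen anchor stress gene (for example Nppa in cardiomyocytes), and to
    test whether the resulting gene program is conserved between two species.
    Provides a negative-binomial single-cell count simulator with planted
    ground truth, Matrix-Market/TSV bundle input and output, QC filtering and
    log normalization, Spearman anchor-correlation ranking with top-K
    selection, homolog mapping and cross-species intersection, Wilcoxon
    stress-response validation with Benjamini-Hochberg adjustment, a
    univariable-to-multivariable clinical regression cascade with a composite
    collagen score, and promoter-interval arithmetic plus IUPAC-consensus and
    position-weight-matrix motif scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
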