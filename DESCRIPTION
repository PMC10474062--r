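Package: statemi
Title: State-Space and Mutual-Information Analysis of Factorial RNA-Seq
    Designs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs low-dimensional transcriptome "state-spaces" by
    singular value decomposition of mean-centered log-normalized counts,
    rotates the selected component plane so the disease axis aligns with
    the x-axis, and compares gene-set sub-spaces to the full transcriptome
    by squared correlation of sample coordinates.  Quantifies how much
    information individual genes carry about experimental condition labels
    via plug-in mutual information on globally max-entropy (equal
    frequency) discretized expression, compares the mutual-information
    density of a gene set against the remaining transcriptome with a
    one-sided rank-sum test (exact enumeration under ties for small
    problems), and checks whether a set's information advantage is
    explained by differential-expression over-representation with a
    hypergeometric test.  Includes a negative-binomial simulator of the
    two-factor (leukemic status x genotype) study design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
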