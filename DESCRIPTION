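Package: coexmi
Title: Gene Coexpression Analysis with Mutual Information and Correlation Ranks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes pairwise coexpression strength of expression profiles
    using both the Pearson correlation coefficient and a plug-in mutual
    information estimator over fixed-width or adaptive equal-frequency
    discretization. Percentile ranks of both measures across all probe pairs
    are obtained through a memory-compressed histogram index (a 35,000-bin
    mutual-information histogram, a 101-entry percentile vector, and a
    precomputed (k/N)log2(k/N) lookup table), enabling rank comparison of
    the two measures, a hybrid linear/nonlinear score, and top-k related-gene
    queries. Includes expression-matrix input/output, detection-call
    co-occurrence rates, a synthetic-data generator with controllable linear,
    monotone-nonlinear, rank-permuted and independent dependency, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
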