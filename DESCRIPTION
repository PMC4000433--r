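Package: mdfdr
Title: Two-Step Hierarchical Hypothesis-Set Testing with OFDR and
    Mixed-Directional FDR Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-dimensional multiple testing where each
    feature (e.g. a gene in a time-course or dose-response experiment)
    carries a set of related hypotheses. A screening p-value is built for
    each set, the Benjamini-Hochberg step-up procedure selects significant
    sets, and a family-wise error rate procedure (Bonferroni, Holm or
    Hochberg) tests the individual hypotheses within each selected set,
    with directional decisions taken from the signs of the test
    statistics. This controls the overall false discovery rate (OFDR) and
    the mixed-directional false discovery rate (mdFDR) at the set level.
    Includes ground-truth error and power metrics, a Monte-Carlo
    simulation study of the procedures under equicorrelated normal
    expression data, and a front-end for testing gene expression over
    ordered categories (successive or baseline contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
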