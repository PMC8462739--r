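Package: tissuesim
Title: Cross-Species Comparison of Tissue-Specific Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls tissue-specific genes (TSGs) from RPKM expression matrices by
    strict high/low thresholds with composite tissue groups, consolidates BLAST
    tabular hits to deterministic best hits per target species, computes a
    "tissue similarity" statistic from min-max normalized homolog expression
    profiles, clusters profiles, exports similarity networks, and runs a
    qRT-PCR delta-Ct testing workflow with a Levene-gated choice between
    parametric ANOVA with Tukey post hoc and Kruskal-Wallis with rank-based
    pairwise comparisons. Includes a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
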