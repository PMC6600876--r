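Package: strucnet
Title: Group Analysis of FA-Weighted Structural Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and group comparison of fractional-anisotropy
    weighted structural connectomes. Builds region-by-region networks from
    streamline-count and mean-FA matrices, applies streamline-count
    thresholds and group-consensus masks, computes weighted graph metrics
    (degree, strength, clustering coefficient, global and local efficiency)
    following Brain Connectivity Toolbox conventions, integrates metrics
    over a threshold range (area under the curve), and runs the matched-pair
    statistical battery (paired and Welch t-tests, Wilcoxon signed-rank,
    Shapiro-Wilk screening, Benjamini-Hochberg and Bonferroni corrections)
    at the edge-class, global, and nodal level. A regression stage relates
    regional graph metrics to regional gene-expression profiles with Cook's
    distance influence diagnostics. A synthetic-cohort generator with
    planted group effects provides ground truth for calibration and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
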