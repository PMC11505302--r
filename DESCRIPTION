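Package: crossdeg
Title: Cross-Species Concordance of Differential Expression on Targeted Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis for targeted count panels
    (NanoString-like) comparing diseased and naive groups by per-gene one-way
    ANOVA on log2 expression with Benjamini-Hochberg adjustment and fold-change
    thresholds; pathway-level summaries of DEG burden; and a cross-species
    gene-set association score: the normalized sum of products of signed ranks
    of gene changes between two differential-expression profiles, bounded in
    [-1, 1], together with the proportional directional concordance of a
    pathway. Includes a synthetic-data generator with known ground truth
    (planted fold changes, pathway structure, and directional concordance) and
    an end-to-end pipeline driver with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
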