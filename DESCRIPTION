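Package: microseek
Title: Detecting Microbial Gene Expression in Short-Read Human RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Alignment-free detection and analysis of bacterial and viral
    gene expression in short-read human RNA-seq. Provides a small
    convolutional neural network that classifies 76-base reads as human,
    viral or bacterial; score-guided greedy seed-and-extend assembly of
    putative microbial contigs; nucleotide and translated six-frame
    annotation of contigs against reference collections; and a cohort
    statistics layer covering differential prevalence (clamped one-tailed
    binomial tests), confounder correction by inverse-probability-weighted
    chi-squared tests, presence-based survival screens, and host gene
    expression screens. A synthetic-data module generates divergent
    origin references, simulated read sets, annotation databases and
    confounded cohort tables so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    Biostrings,
    xgboost,
    survival,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
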