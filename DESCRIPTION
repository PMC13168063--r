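Package: saltrank
Title: Multi-Gradient Salt-Tolerance Screening and Ranking of Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for evaluating salt tolerance of crop
    germplasm from multi-gradient NaCl trials: phenotype quality control and
    replicate aggregation, salt tolerance index (stress/control ratio),
    dose-response summaries, factorial genotype-by-salt ANOVA, Pearson trait
    correlations with significance stars, Z-score standardized wide matrices,
    Euclidean distances, UPGMA dendrograms with Newick export, PCA, K-means
    grouping, TOPSIS composite ranking with extreme-genotype selection, and
    validation arithmetic (2^-ddCt relative expression, K+/Na+ ratios, group
    comparisons). Includes a synthetic-trial generator with known ground
    truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
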