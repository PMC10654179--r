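Package: macawpop
Title: Post-Variant-Calling Population Genomics for Small Macaw Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the post-variant-calling analyses used in
    small-panel population genomics of scarlet macaw subspecies and similar
    systems: composable VCF hard filters and neutral-site selection, windowed
    r-squared LD thinning, Nei-style per-sample nucleotide diversity and
    pairwise divergence (pi, dXY, dA), genotype-matrix PCA, and the
    frequency-weighted ABBA/BABA D statistic with block-jackknife
    significance. A Balding-Nichols genotype simulator emulates a
    four-population tree with per-branch drift and an optional introgression
    pulse, so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
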