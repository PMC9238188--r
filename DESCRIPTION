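Package: redunrank
Title: Predictor Rank Changes Under Multi-Omic Integration for Phenotype
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven pipeline to study why concatenating genomic
    (SNP) and transcriptomic predictors can improve phenotype prediction.
    Provides a synthetic-data generator with planted cis/trans eQTL
    architecture (including regulatory hubs), field-phenotype adjustment for
    block and first-order autoregressive spatial heterogeneity with AIC model
    selection, transcript count filtering, TMM/log-CPM normalisation and
    genotypic BLUP extraction, a multi-locus mixed-model eQTL scan with
    forward inclusion, backward elimination and mBonf model selection,
    positional cis/trans classification of associations, ridge-regression
    prediction (G, T and G+T models) under repeated nested cross-validation,
    the per-category mean rank-change statistic of squared effects with its
    cross-trait regression against integration advantage, and gene-ontology
    enrichment by Fisher's exact test with the elim decorrelation algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    edgeR,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
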