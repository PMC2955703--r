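Package: phenoDomain
Title: Phenotype Prediction for Prokaryotes from Protein Domain
    Frequency Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discriminative prediction of prokaryotic phenotypes (endospore
    formation, Gram stain, motility, oxygen requirement, ...) directly from
    genome-wide protein domain frequency profiles. Implements the balanced
    regularized least-squares classifier (RLSC) with a linear kernel in its
    dual form, recovery of the primal discriminant in domain-profile space,
    taxonomy-aware (genus-partitioned) and random validation protocols,
    regularization selection by mean precision-recall AUC, ranking of
    discriminative Pfam domain families, UPGMA clustering of their
    phylogenetic profiles, a synthetic data generator with planted
    phenotype-linked domain modules, and an annotation-discrepancy audit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'evaluation-experiments.R'
    'evaluation-metrics.R'
    'evaluation-splits.R'
    'features.R'
    'model-io.R'
    'phenoDomain-package.R'
    'pipeline.R'
    'profiles-io.R'
    'profiles.R'
    'rlsc.R'
    'synthetic.R'
    'utils.R'
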