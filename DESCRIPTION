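Package: merlin
Title: Modular Gene Regulatory Network Inference from Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers per-gene transcriptional regulatory programs from a
    gene-by-sample expression matrix under a probabilistic module prior
    that encourages, without forcing, genes in the same expression module
    to share regulators. Each gene is modelled as a conditional Gaussian
    of its selected regulators (a dependency network scored by
    pseudo-likelihood), edges carry a logistic structure prior whose
    feature is the fraction of a regulator's current targets inside the
    candidate gene's module, and module membership is re-estimated by
    threshold-stopped average-linkage clustering of a combined
    co-expression and regulatory-similarity distance. Includes a
    linear-Gaussian steady-state knockout simulator for generating
    modular ground-truth benchmarks, edge-, regulator- and module-based
    evaluation metrics (AUPR, fold enrichment, hypergeometric target
    overlap, regulatory modularity, silhouette), gene-set enrichment
    utilities, expression preprocessing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core-model.R'
    'preprocess.R'
    'evaluation.R'
    'simulator.R'
    'learner.R'
    'io.R'
    'cli.R'
    'merlin-package.R'
    'methods.R'
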