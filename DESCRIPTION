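Package: oriclass
Title: Replication Origin Classification from DNA Sequence Composition
Version: 0.1.0
Authors@R:
    person("Origin", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Identifies eukaryotic DNA replication origins from fixed-length
    sequence windows. Provides k-tuple TF-IDF sequence encoding,
    base-composition (GC/AT skew and profile) features, series-correlation
    pseudo k-tuple nucleotide composition (PseKNC type II), two-step
    F-score / incremental feature selection, and repeated stratified
    cross-validated classification (multi-layer perceptron, kernel SVM,
    k-nearest neighbours, CART, Gaussian naive Bayes, gradient boosted
    trees) with sensitivity, specificity, accuracy, Matthews correlation
    and AUC reporting. Includes a synthetic sequence generator with planted
    motifs and compositional skew so the full pipeline is testable without
    external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    FNN,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
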