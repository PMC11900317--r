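Package: kinasepred
Title: Ligand-Based Kinase Activity Prediction with Explainable Fingerprint Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curates small-molecule activity tables into balanced
    kinase-family datasets, computes Morgan, path-subgraph and 881-key
    substructure fingerprints with full bit-to-atom provenance, trains and
    selects random-forest, Gaussian naive Bayes and multi-layer perceptron
    classifiers by MCC-scored grid search, explains predictions at atom
    level via Kernel SHAP retro-mapping, screens compound libraries with
    structural clustering of hits, and builds per-target random-forest
    models with class-imbalance diagnostics. Includes a deterministic
    synthetic fixture generator (planted-substructure actives vs decoys) so
    the full pipeline runs without external chemical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
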