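Package: ligandscreen
Title: Ligand-Based Virtual Screening with Fingerprint QSAR Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for ligand-based virtual screening of small
    molecules against a protein target: SMILES curation and standardization,
    molecular descriptor and fingerprint computation (Morgan, path, MACCS,
    atom-pair, topological-torsion), Tanimoto similarity, chemical-space
    embedding (exact t-SNE) with Ward.D2 hierarchical clustering and
    representative selection, a fingerprint-by-model evaluation grid (random
    forest, SVM, MLP, gradient boosting) with five-fold cross-validation and
    an eight-metric suite, library screening with the selected model, and
    prioritization of hits from tabulated docking scores and MM-PBSA
    binding-energy components. A seeded synthetic benchmark generator with a
    planted structural motif makes every stage testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    ranger,
    e1071,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
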