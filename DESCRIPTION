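Package: idrbind
Title: Prediction of RNA-, DNA- and Protein-Binding Residues in Intrinsically
    Disordered Regions
Version: 0.1.0
Authors@R:
    person("Ida", "Reiner", email = "ida.reiner@example.org", role = c("aut", "cre"))
Description: Sequence-based, per-residue prediction of RNA-, DNA- and
    protein-binding mediated by intrinsic disorder. Proteins are represented by
    sliding-window physicochemical profiles (amino-acid scales, window
    composition, Shannon complexity, putative disorder and secondary
    structure), turned into near-versus-remote contrast features over
    function-specific windows, and scored by ridge-penalized logistic
    regression. A homology layer transfers annotations from the training
    library by local alignment and merges them with the regression
    propensities. The package includes the full training, feature-selection,
    evaluation (per-residue ROC/AUC, subset-resampling significance,
    control-region false-positive rates) and proteome-level validation
    machinery, plus a seeded synthetic-corpus generator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
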