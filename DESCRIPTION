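Package: selcarb
Title: Selective Prediction of Protein Carbonylation Sites with
    Cross-Prediction Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein carbonylation sites on lysine, proline,
    arginine and threonine residues while suppressing cross-prediction of
    ligand interaction sites. Provides sliding-window segment extraction,
    physicochemical/PSSM/embedding feature encoding, information-gain-ratio
    motif discovery, a two-module attention network (short-distance
    convolutional attention over segment-level physicochemical features and
    long-distance self-attention over protein-level evolutionary profiles)
    trained with transfer learning and a class-specific focal loss, a
    seeded synthetic-data generator, and a cross-prediction-aware
    evaluation framework (CPR/OPR ratios, CP/OP curves, partial-AUC
    ratios, bootstrap significance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nortest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
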