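Package: mfpep
Title: Multi-Label Functional Peptide Prediction with Label-Graph Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts multiple bioactivities (antimicrobial, anticancer,
    antidiabetic, antihypertensive, anti-inflammatory) for short peptides
    from sequence embeddings. A per-label node encoder projects each
    peptide embedding onto one node of a fully connected label graph,
    multi-head graph attention models label interdependencies, and
    per-node sigmoid classifiers emit label probabilities. Training uses
    binary cross-entropy plus fast-gradient-method (FGM) adversarial
    perturbations of the input embedding; predictions from several
    embedding backends can be combined by weighted ensembling. Includes
    multi-label evaluation metrics (aiming/precision, coverage, accuracy,
    absolute true, absolute false), per-label binary metrics, in-silico
    saturation-mutagenesis scanning, and a synthetic motif-based dataset
    generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
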