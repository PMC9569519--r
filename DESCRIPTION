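Package: neoimm
Title: Neoantigen Immunogenicity Prediction from Peptide-MHC Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the immunogenicity of candidate neoepitopes from
    peptide sequence, MHC class I allele, binding affinity (IC50), TAP
    transport efficiency and transcript abundance. Provides one-hot
    encoding of peptides and MHC pseudo-sequences, curation of T-cell
    assay tables into labelled training data, a two-branch convolutional
    neural network trained with class-weighted binary cross-entropy and
    dual early stopping, five classical machine-learning baselines,
    candidate neoepitope filtering and ranking, and a seeded synthetic
    assay generator with a planted immunogenicity rule for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    glmnet,
    e1071,
    xgboost,
    randomForest,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
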