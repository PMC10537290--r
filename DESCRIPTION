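Package: adverank
Title: Drug Side-Effect Association Prediction with Heterogeneous Graph
    Attention and Capsule Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts and ranks associations between drugs and side-effects
    from a binary association matrix and drug/side-effect similarity
    matrices. Two drug-side-effect heterogeneous graphs (one per drug
    similarity modality) are encoded with a multi-head graph transformer
    that attends over typed neighbor sets and fuses neighbor categories and
    graphs with learned attention; in parallel, a multi-view capsule network
    with dynamic routing scores each drug-side-effect pair from its stacked
    raw pair embeddings. The two association probabilities are fused into a
    final score. Includes balanced-negative-sampling five-fold
    cross-validation with per-drug AUC, AUPR, and top-k recall, a synthetic
    block-structured data generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
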