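Package: foldswitch
Title: Dual-Conformation Assessment of Structure-Prediction Ensembles for
    Fold-Switching Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for judging structure-prediction ensembles of
    fold-switching proteins, which adopt two distinct experimentally
    determined conformations. Provides region-restricted TM-score and
    Kabsch RMSD classification of predicted models against both reference
    folds, plDDT-based confidence reranking and Top1/Top10/All tabulation,
    Easy/Complex difficulty labelling, SPEACH-style alanine masking of
    multiple sequence alignments, AF2Rank-style template preparation and
    composite scoring, normalized B-factor flexibility and contact-map
    probes, and a synthetic-data generator that builds toy fold-switch
    pairs, prediction ensembles with planted label mixtures and confidence
    polarity, and toy alignments, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
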