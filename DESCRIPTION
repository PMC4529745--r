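Package: secloc
Title: Consensus Subcellular Location Assignment and Secretome Sizing for
    Metazoan Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based consensus assignment of protein subcellular
    locations from curated UniProtKB annotation and the batch outputs of
    seven sequence-based predictors (SignalP 3 and 4, Phobius, TargetP,
    WoLF PSORT, TMHMM 2 and FragAnchor). Proteins are placed into sixteen
    location categories with secreted-confidence tiers (curated, highly
    likely, likely, weakly likely), membrane/non-membrane splits driven by
    transmembrane-helix topology, ER-retention (KDEL-type, PROSITE
    PS00014) motif scanning, and GPI-anchor flagging. Includes the
    single-location Swiss-Prot benchmark construction with
    sensitivity/specificity/Matthews-correlation evaluation of arbitrary
    predictor-combination rules, per-species secretome statistics with the
    secretome-vs-proteome regression, and a synthetic proteome/predictor
    simulator with controllable per-tool error rates for end-to-end
    validation without the licensed predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
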