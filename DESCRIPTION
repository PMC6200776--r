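Package: bretfit
Title: Ligand-Binding Analysis for Live-Cell NanoBRET Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for live-cell bioluminescence resonance energy
    transfer (BRET) ligand-binding assays of receptor tyrosine kinases and
    their co-receptors. Implements one-site saturation binding with joint
    non-specific-well fitting, global exponential-association kinetics
    (shared k_on/k_off across ligand concentrations), competition binding
    with Cheng-Prusoff Ki estimation and the IC50-versus-probe-concentration
    regression, four-parameter concentration-response fitting, half-time and
    residence-time arithmetic, and cross-experiment aggregation to
    mean +/- SEM summaries. Includes a synthetic plate-data generator that
    emulates the standard saturation, association, competition and
    concentration-response plate designs for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
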