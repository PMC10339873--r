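Package: fgmassay
Title: Enzyme Immunoassay Quantification and Longitudinal Analysis of
    Fecal Glucocorticoid Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Workflow for non-invasive stress monitoring with fecal
    glucocorticoid metabolites (FGMs) measured by competitive enzyme
    immunoassay (EIA). Models 96-well plates with duplicate-well quality
    control, fits four-parameter logistic standard curves with closed-form
    back-calculation, converts extract concentrations to ng per g dry feces
    with below-detection imputation, runs analytical validation
    (parallelism of serially diluted pools and spike-recovery accuracy),
    and analyses longitudinal per-individual series: SD-trimmed baselines,
    2-SD peak detection, acute/chronic dual-metabolite stress events, and
    matching of events to husbandry notes. A synthetic-data generator with
    a known ground-truth ledger supports end-to-end testing without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
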