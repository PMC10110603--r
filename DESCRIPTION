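Package: chloropatch
Title: Chloride Homeostasis and Epileptiform Activity Analysis for
    Patch-Clamp and EEG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for neuronal chloride homeostasis studies:
    estimation of the GABA-A reversal potential from stepped-potential
    voltage-clamp recordings with series-resistance correction, conversion
    to intracellular chloride concentration via the Nernst equation,
    detection and kinetic characterization of miniature postsynaptic
    currents, tonic GABA current quantification from antagonist-induced
    baseline shifts, rule-based EEG epileptiform spike and discharge
    detection with relative band-power spectra, and the accompanying
    behavioral index and variance-conditional statistics.  Includes seeded
    synthetic-data generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
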