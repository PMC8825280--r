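Package: gutsense
Title: Quantification of Gut-Brain Sensory Transduction Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for studies of gut epithelial sensory (neuropod)
    cells and their vagal readout. Converts extracellular whole-nerve voltage
    recordings into spike trains, Gaussian-kernel firing rates and
    baseline-normalized response metrics; classifies per-cell calcium
    responses from ratiometric (Fluo-4/Fura Red) and single-channel (GCaMP)
    fluorescence with a KCl viability gate and summarizes responder overlap;
    processes single-cell RT-qPCR quantification-cycle matrices (quality
    control, relative quantities, per-gene normalization, differential
    expression, receptor coexpression classes); cleans phenotyping-cage
    intake streams and computes two-bottle preference and optogenetic
    stimulation schedules; and fits fiber-optic cut-back attenuation.
    Includes seeded synthetic-data generators with ground-truth labels for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
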