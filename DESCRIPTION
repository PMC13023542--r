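Package: apneaseg
Title: Apnea-Hypopnea Event Segmentation for PSG and FMCW Radar Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for detecting sleep apnea and hypopnea events from
    respiratory effort signals. Provides a seeded generator of synthetic
    polysomnography-like (PSG) nights and FMCW-radar-like range-bin cubes
    with known ground truth; phase-based radar respiration extraction
    (DC removal, phase unwrapping, band-pass filtering, orthogonal ridge
    projection with overlap-add); annotation parsing, event cleaning,
    label rasterization, robust normalization and sliding-window tensor
    construction; a 1D residual U-Net with an ASPP-lite module and a
    transformer bottleneck for dense per-sample event segmentation,
    implemented with exact analytic gradients and an Adam optimizer;
    PSG-to-radar transfer fine-tuning with partial layer freezing and
    frozen batch normalization; and event-level (interval-IoU matching)
    and recording-level (apnea-hypopnea index, severity, Cohen's kappa)
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
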