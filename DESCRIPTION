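Package: dendrocalc
Title: Quantification of Dendritic and Spine Calcium Transients from
    Two-Photon Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium-imaging experiments on
    cortical pyramidal neurons: extraction of per-ROI fluorescence traces from
    image stacks with vessel-background subtraction, percentile-baseline
    dF/F0 computation, threshold-based detection and characterization of
    somatic, dendritic and spine calcium transients (duration, peak,
    integrated activity, prolonged/large-amplitude classification),
    spine-specific signal isolation by scaled subtraction of the dendritic
    shaft signal, paired before/after comparison of spine peaks around
    dendritic plateau events, two-channel intensity-ratio spine-head
    morphometry with turnover accounting, and normality-routed group
    statistics. Includes a synthetic-data generator with full ground truth so
    that every stage of the pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    nortest,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
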