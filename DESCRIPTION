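Package: issread
Title: In Situ Sequencing Readout: Simulation, Spot Detection, Base
    Calling and Assay Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the image-analysis readout of targeted in situ
    sequencing (ISS) experiments, in which barcoded padlock-probe
    amplicons (rolling circle products, RCPs) are detected as
    diffraction-limited fluorescent spots and their barcodes are read
    over successive sequencing-by-ligation cycles.  Provides a seeded
    synthetic multi-cycle, multi-channel image generator with full
    ground truth; anchor-channel spot detection with annulus-based
    signal-to-noise estimation; DAPI nucleus segmentation and
    spot-to-cell assignment; per-cycle base calling with max/sum
    quality scores, quality-threshold read assembly and codebook
    decoding; summary metrics (RCP yield, reads per cell, sequencing
    accuracy, performance efficiency against a paired control, stacked
    per-base quality, stripping efficiency); and a small mass-transport
    module for diffusion times, diffusive reach within an enzyme
    half-life, and reaction-chamber volume and dose accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
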