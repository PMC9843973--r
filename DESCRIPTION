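Package: mirlipid
Title: Multiscale Infrared Spectroscopy Analysis of Fungal Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiscale mid-infrared analysis of lipid accumulation
    in oleaginous, dimorphic fungi. Covers bulk-biomass FTIR chemometrics
    (extended multiplicative signal correction, Savitzky-Golay derivatives,
    ANOVA-PCA effect partitioning of designed campaigns), comparison of
    transmission and attenuated-total-reflectance measurements (common-axis
    alignment, second-derivative peak picking, peak matching and lipid band
    ratios), focal-plane-array hyperspectral image processing (outlier repair,
    PCA plus k-means segmentation, lipid-to-protein ratio maps) and AFM-IR
    nanospectroscopy map correction (plane levelling, scan-line artefact
    repair, rigid drift registration, laser-power normalisation, log-ratio
    maps). A forward simulator generates bulk spectra, hyperspectral cubes and
    AFM-IR scenes with known ground truth, including an evanescent-wave
    penetration-depth model for ATR, so every processing stage can be
    validated by recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
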