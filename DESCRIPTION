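Package: laminaresp
Title: Respiration-Informed Macrovascular Bias Removal for Laminar fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps respiration-related signal fluctuations in high-resolution
    laminar fMRI directly from the image time series, and uses that map to
    exclude macrovascular-dominated voxels before cortical-depth analysis.
    Implements interleaved blood-nulled/control (VAPER) and BOLD contrast
    computation with frame censoring, an image-derived respiration-effect map
    (outlier-fraction detection of respiration-variation time points),
    deep-breath and breath-hold block analyses with breath-phase ROI fitting,
    equi-volume cortical depth and column parcellation on volumetric
    segmentations, percent-signal-change GLMs and laminar profiles before and
    after voxel exclusion, node-wise vessel-density association, a
    neighbor-correlation blurring kernel with FWHM estimation, and a seeded
    synthetic laminar-fMRI phantom with planted vessels and
    respiration-coupled physiology for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tibble,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
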