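Package: organoidqpi
Title: Label-Free Organoid Characterization from Quantitative Oblique
    Back-Illumination Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free characterization of neural organoids
    imaged by quantitative oblique back-illumination microscopy (qOBM):
    differential phase contrast formation and regularized phase
    reconstruction, refractive-index conversion and high-RI (lipid and
    nucleic material) segmentation, whole-organoid and neural-rosette
    morphometrics, tile-wise texture/fractal/Fourier/autocorrelation
    feature extraction with mRMR, neighborhood component analysis and
    chi-square feature-selection consensus, Welch-t and variance-F group
    comparisons, and Oil-Red-O histology quantification by color
    deconvolution. Includes a synthetic organoid-phantom generator and a
    two-group longitudinal cohort simulator so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
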