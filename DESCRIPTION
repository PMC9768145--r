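Package: boneRad
Title: Photoelectron-Mediated X-Ray Radiation Damage Analysis in Mineralized Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying primary X-ray radiation damage in bone and
    other mineralized collagenous tissues. Implements a single-scattering
    Monte-Carlo model of photoelectron transport in bone-like materials, a
    convolution-based model of damage spread around a microfocus beam
    (beam-profile convolved with the photoelectron penetration-depth
    distribution, thresholded to give relative damaged areas and volumes),
    quantification of collagen damage imprints in second-harmonic-generation
    (SHG) image stacks, and residual-strain relaxation analysis of the
    carbonated-apatite (002) reflection from 2D diffraction frames. Seeded
    synthetic-data generators emulate SHG stacks, Debye-ring frames, and
    damage/strain time series so that every pipeline stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
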