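Package: psmquant
Title: Volumetric Quantification of Whole-Mount HCR Fluorescence in the
    Presomitic Mesoderm
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of whole-mount multiplexed
    fluorescence in situ (HCR) image stacks of the early mouse
    presomitic mesoderm (PSM): flat-field shading correction and
    per-probe baseline calibration, marker-defined 3D volumetric
    masking with volume-targeted automatic thresholding, masked
    intensity-density measurement, punctate-signal spot modeling with
    fixed intensity binning, oscillation-phase classification of
    striped segmentation-clock expression, and cohort-level genotype
    statistics. Includes a synthetic 3D embryo phantom generator with
    full ground truth so every stage of the pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, ImageImport, Visualization
RoxygenNote: 7.3.3
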