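Package: aqueflow
Title: Cerebrospinal Fluid Flow Quantification from Cine Phase-Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pulsatile cerebrospinal fluid flow through the aqueduct
    of Sylvius from gated 2D cine phase-contrast MRI. Provides a ground-truthed
    pulsatile laminar-flow phantom generator, NIfTI+sidecar input/output,
    phase-to-velocity conversion with static-tissue (no-flow area) background
    correction, three semiautomatic lumen segmentation strategies (border-seeded
    local thresholding, manual-contour refinement by Otsu thresholding, and
    seeded region growing), the full set of hydrodynamic measures (cross-sectional
    area, mean and maximal velocity, flow rate, caudal/cranial/net volumes per
    cardiac cycle), segmentation-overlap (Dice) and repeatability (intraclass
    correlation) statistics with standard classification bands, and a synthetic
    cohort framework for general-linear-model and repeated-measures ANOVA
    reproducibility analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    EBImage,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
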