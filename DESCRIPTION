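Package: fkodil
Title: Tumor Cell Density Inference by Optimizing a Discrete Fisher-Kolmogorov Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint inference of a four-dimensional tumor-cell-density field and
    Fisher-Kolmogorov reaction-diffusion growth parameters from a single imaging
    time point (tumor segmentation labels plus an optional amino-acid PET volume).
    The unknown space-time density is stored on a multiresolution grid and fitted
    by gradient-based minimization of a discrete loss that softly combines the
    Crank-Nicolson residual of the growth equation, a focal Gaussian initial
    condition, and sigmoid imaging-model terms linking density to segmentations
    and PET signal. Includes a forward finite-difference solver, a synthetic
    patient generator (threshold-derived segmentations, spatially correlated PET
    noise, partial-volume degradation), and radiotherapy-planning evaluation
    metrics (Dice, PET correlation, margin-based clinical target volumes,
    volume-matched plans, recurrence coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
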