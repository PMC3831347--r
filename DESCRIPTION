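Package: emtseg
Title: Iterative EM Tissue Classification, Bias-Field Correction and
    Registration for Multi-Modal Brain MRI
Version: 0.1.0
Authors@R:
    person("Eun", "Park", email = "epark@example.org", role = c("aut", "cre"))
Description: Joint iterative framework for brain MR image analysis:
    multi-modal Gaussian-mixture tissue classification by
    expectation-maximization with atlas spatial priors, region-specific
    quantile intensity-context constraints, smooth polynomial bias-field
    (inhomogeneity) estimation in log-intensity space, rigid/affine
    registration with a pluggable deformable backend, a BrainWeb-style
    synthetic phantom generator, and Dice / modified-Hausdorff evaluation
    utilities.  Volumes are read and written as NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
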