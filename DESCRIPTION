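Package: optrheo
Title: Optical Rheology of Fibrous Tissue from Polarization-Sensitive OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates tissue birefringence from Jones-matrix
    polarization-sensitive optical coherence tomography volumes (phase-aligned
    Jones averaging, local round-trip matrices, Lu-Chipman retardance,
    Monte-Carlo noise-bias correction, degree-of-optic-axis-uniformity
    masking), extracts elastic parameters from uniaxial stress-strain records
    via an exponential constitutive model, and correlates birefringence with
    elasticity across a cohort of scleral samples. Includes ground-truth
    synthetic generators for phantoms, tensile records and linked cohorts so
    that every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
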