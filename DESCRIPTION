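Package: petlong
Title: Partial Volume Correction and Longitudinal Mixed-Effects Analysis of Tau PET SUVR
Version: 0.1.0
Authors@R:
    person("petlong", "developers", email = "petlong@example.org", role = c("aut", "cre"))
Description: Tools for evaluating partial-volume-correction (PVC) methods and
    linear mixed-effects (LMEM) analysis of longitudinal tau PET standardized
    uptake value ratios (SUVR). Provides digital brain phantoms with known
    ground truth, five PVC algorithms (Meltzer 2-compartment, Mueller-Gartner
    3-compartment, van Cittert deconvolution, geometric transfer matrix, and
    region-based voxelwise correction), region-of-interest SUVR quantification
    with tau-level stratification, a longitudinal cohort simulator, and
    mixed-model estimation of annualized percent SUVR change, within-subject
    variability, group-separation t-scores, and longitudinal effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
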