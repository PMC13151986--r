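Package: pbdefc
Title: Gestational PBDE Exposure and Adolescent Resting-State Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for prospective-cohort analyses
    linking gestational polybrominated diphenyl ether (PBDE) serum
    concentrations to adolescent resting-state functional connectivity.
    Includes exposure preparation (limit-of-detection substitution, lipid
    normalization, congener summation, log2 transformation), fMRI
    time-series denoising (motion scrubbing, CompCor-style nuisance
    regression, detrending, band-pass filtering, spatial smoothing),
    voxelwise local and global correlation mapping (LCOR/GCOR),
    exposure-connectivity general linear models with permutation
    cluster-extent inference, univariate mediation with bootstrap
    inference, and high-dimensional multivariate mediation via principal
    directions of mediation.  A seeded synthetic-cohort generator with
    known planted effects makes every stage testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
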