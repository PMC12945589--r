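Package: strainmap
Title: Normative Brain Shear-Strain Vulnerability Mapping and
    Strain-Stratified Diffusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping normative shear-strain concentration in the
    brain from magnetic resonance elastography (MRE) and testing whether
    strain concentration predicts diffusion-MRI tissue disruption in mild
    traumatic brain injury. Computes octahedral shear strain, maximum
    principal strain and damping ratio from voxelwise strain-tensor and
    complex-modulus fields; defines high-strain regions by voxelwise
    one-sample t-tests with Benjamini-Hochberg false-discovery-rate and
    effect-size thresholds, with leave-one-out cross-validation; derives
    apparent fiber density (AFD) from single-shell diffusion MRI via
    constrained spherical deconvolution; and fits strain-stratified
    group statistics (OSS-binned mixed-effects models, mixed-design
    ANOVAs, region-ratio tests). A synthetic-data module generates
    co-registered cohorts with known ground truth so the whole pipeline
    is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    pracma,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
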