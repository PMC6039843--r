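Package: svdstrat
Title: Stratification of Preclinical Vascular Dementia in Small Vessel Disease MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for stratifying symptomatic cerebral
    small vessel disease (SVD) cohorts by dementia risk from template-space MRI
    derivatives. Provides whole-brain volumetrics (tissue volumes, TCV, TIV, the
    SVDp vascular-burden percentage, annualized rates), lacune overlap and
    atlas-ROI incidence analysis with rater-reliability statistics, voxel-based
    morphometry group contrasts with covariate adjustment and max-statistic
    permutation family-wise error control (Freedman-Lane), longitudinal
    divergence-to-rate-map fitting with warped-weighted-average smoothing,
    leave-one-out linear support-vector-machine prediction of conversion with
    training-fold confound regression and permutation significance, Ward-linkage
    anatomical subtyping from Jacobian determinant maps, cognitive index
    construction with linear-mixed-effect slope estimation, and Kaplan-Meier /
    log-rank survival analysis stratified by prediction and vascular burden.
    A synthetic cohort generator emulates the assumed data structure (template
    grid tissue maps, lacunes, Jacobians, divergence series, cognition, and
    conversion outcomes) so every stage is exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    e1071,
    lme4,
    survival,
    stats,
    utils
Suggests:
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
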