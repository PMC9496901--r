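Package: deltarad
Title: Longitudinal Prostate mpMRI Radiomics and Delta-Radiomics Outcome Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for longitudinal multiparametric prostate
    MRI radiomics. Derives tumor, peritumoral-ring, and normally-appearing
    tissue regions from prostate/zone/tumor masks; extracts first-order
    apparent-diffusion-coefficient statistics; fits the Extended Tofts
    pharmacokinetic model with a Parker population arterial input function to
    ROI-averaged dynamic contrast-enhanced curves; summarizes longitudinal
    percent changes with two-sample t-tests; and predicts endpoint-biopsy
    positivity from scan-point and delta features via screened, decorrelated
    multivariate logistic regression evaluated by leave-one-out
    cross-validation. Includes a synthetic digital-phantom cohort generator so
    the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    minpack.lm,
    pROC,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
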