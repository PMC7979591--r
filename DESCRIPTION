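Package: hepiron
Title: Hepatic Iron Quantification from Multi-Echo Gradient-Echo MRI
Version: 0.1.0
Authors@R:
    person("hepiron", "maintainers", email = "hepiron@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for R2*-based liver iron
    quantification at 1.5 T. Implements the chemical-shift-encoded
    multi-echo gradient-echo signal model with multi-peak fat dephasing
    and a Rician-expectation noise correction; three R2* estimators
    (truncation-model mono-exponential fit, magnitude Dixon water/fat
    fit, noise-corrected first-moment fit) with fat/water swap detection;
    a synthetic phantom and patient-cohort generator; ROI-based patient
    summaries; liver iron concentration (LIC) calibration equations with
    affine cross-calibration and iron-burden classification; and
    method-agreement statistics (linear regression, Bland-Altman, Lin's
    concordance correlation, contingency tables, overall percent
    agreement, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
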