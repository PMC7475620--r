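Package: jointpred
Title: Joint Longitudinal-Survival Models and Dynamic Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modeling of a longitudinal biomarker and a time-to-event
    outcome under two frameworks: the shared random-effect model (SREM), in
    which the random intercept and slope of the biomarker trajectory enter a
    Weibull proportional-hazards model, and the joint latent class model
    (JLCM), a finite mixture with class-specific trajectories and
    class-proportional hazards. Provides BIC-based class enumeration, a
    conditional-independence score test, empirical-Bayes random-effect
    posteriors, individual dynamic risk prediction over landmark windows,
    time-dependent ROC/AUC model comparison, and a synthetic cohort
    generator emulating registry-style HIV/CD4 follow-up data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    lme4,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
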