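Package: psyvalid
Title: Psychometric Validation of Likert Symptom Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the psychometric validation of short Likert-type
    symptom severity scales such as the PHQ-9 and GAD-7.  Fits competing
    confirmatory factor models on covariance and mean structures by
    maximum likelihood with sandwich (Huber-White) standard errors and
    mean-scaled test statistics, computes bifactor-(S-1) model-based
    reliability (total, hierarchical and hierarchical-subscale omega),
    runs Haberman's proportional-reduction-in-mean-squared-error
    subscore value-added analysis with Olkin's Z, walks the multigroup
    measurement-invariance ladder (configural, metric, scalar, factor
    variance, residual) with explicit decision rules and
    partial-invariance search, and contrasts unit-weighted with
    latent-mean standardized group effect sizes.  Includes a simulator
    for 4-point Likert item responses generated from population factor
    models with plantable invariance violations, plus Little's MCAR
    test and complete-case utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
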