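Package: ghostsurv
Title: Hidden Observations Behind Parametric Survival Model Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the statistical efficiency advantage of parametric
    survival models (exponential, Weibull, generalized gamma) over the
    nonparametric Nelson-Aalen cumulative-risk estimator as an effective
    sample size: uniform pseudo-observations ("ghosts") are added to the
    nonparametric sample, as equal per-subject case-weight increments, until
    its delta-method 95% confidence-limit width at a target time undercuts
    the parametric model's. Includes weighted Nelson-Aalen estimation,
    censored maximum-likelihood fitting of the three nested accelerated
    failure time families with delta-method risk confidence limits, a seeded
    synthetic-cohort generator emulating an HIV cohort with loss to
    follow-up and administrative censoring, and efficiency comparison
    metrics (confidence-limit width at a time, average width over event
    times, root mean square error against the nonparametric reference).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    flexsurv,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
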