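Package: visitjm
Title: Joint Models and Weighted Estimators for Longitudinal Data with
    Informative Visiting Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal outcomes observed at
    irregular, outcome-dependent visit times, as arise in electronic
    health records. Implements maximum-likelihood estimation of a joint
    model linking a Weibull recurrent-event (gap-time) visiting process
    to a Gaussian longitudinal outcome through a shared random effect;
    linear mixed-model comparators adjusting for visit counts; and a
    two-stage inverse-intensity-of-visiting weighted marginal estimator
    based on an Andersen-Gill gap-time intensity model. Includes the
    simulators, analytic reference quantities, and Monte Carlo
    simulation-study machinery (bias, coverage, mean squared error with
    Monte Carlo standard errors) needed to evaluate these estimators
    under informative and non-informative visiting processes.
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
    sandwich,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
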