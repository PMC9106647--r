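Package: anchortm
Title: Distributional Anchor Regression with Transformation Models
Version: 0.1.0
Authors@R:
    person("anchortm", "maintainers", email = "anchortm@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood transformation models for continuous,
    censored and ordinal responses, regularized by a causal penalty that
    de-correlates exogenous anchor (environment) variables from score
    residuals. Provides Bernstein-polynomial, linear and ordinal response
    bases with monotone reparametrization, probit/logit/minimum-extreme-value
    inverse links, closed-form linear L2 anchor regression, structural
    equation simulators with do- and push-interventions, worst-case
    negative-log-likelihood evaluation protocols including
    leave-one-environment-out cross-validation, and a command-line
    interface for simulation, fitting and evaluation.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
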