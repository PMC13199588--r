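Package: hfrpam
Title: Human Factors Risk Probability Assessment for Physical Literacy Panels
Version: 1.0.0
Authors@R:
    person("HFRPAM", "Maintainers", email = "maintainers@hfrpam.org", role = c("aut", "cre"))
Description: Expert-elicitation risk modelling for the human factors of
    physical literacy. Takes a panel of 5-point Likert ratings over the
    two-stage / six-attribute physical-literacy structure (two primary and
    six secondary factors, X1-X8) and runs a five-stage pipeline:
    psychometric quality control (Cronbach's alpha, content validity
    indices, test-retest ICC, descriptive moments), counting-based Bayesian
    risk posteriors with ISO-31000 probability banding, entropy-reduction
    risk weights, mutual-information sensitivity values, and an
    efficiency-thoroughness trade-off optimization index with activity
    sequencing and optimization-path labelling. Includes a Gaussian-copula
    simulator for ordinal Likert panels so every stage is testable without
    access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
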