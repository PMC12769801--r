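Package: asthmapac
Title: Rule-Based Asthma Ascertainment from Clinical Notes Using
    Predetermined Asthma Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A computable phenotype for asthma built on the Predetermined
    Asthma Criteria (PAC). Reads free-text clinical notes and structured
    observations (labs, pulmonary function tests, smoking status), extracts
    asserted asthma-relevant concepts with negation, hypothetical and
    experiencer handling under section constraints, evaluates the PAC
    conditions and exclusions cumulatively over each patient's timeline,
    assigns definite/probable/no-asthma status with an incident index date,
    and validates results against a reference standard with Cohen's kappa,
    agreement, sensitivity, specificity, predictive values, and two-by-two
    odds ratios with Wald confidence intervals. Includes a seeded generator
    of labeled synthetic note corpora for end-to-end testing without any
    protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
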