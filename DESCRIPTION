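Package: gxesim
Title: Simulation of Case-Control Data with Gene-Environment Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates simulated case-control data sets in which disease
    status is driven by an interaction between a genetic and an
    environmental factor. Disease risk follows a multi-logistic penetrance
    model (one logistic risk curve per genotype combination); a
    constraint-based solver converts standard epidemiological inputs
    (disease prevalence, genotype relative risk, inheritance weight,
    environmental odds ratio) into model coefficients under qualitative
    interaction-model constraints (genetic-only, environmental-only,
    additive, and gene-modulated response models). Includes Hardy-Weinberg
    genotype sampling, Monte Carlo disease-status assignment, empirical
    validation summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
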