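Package: seqmonitor
Title: Group-Sequential and Bayesian Interim Monitoring for Two-Arm Binary Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation tools for interim monitoring of two-arm
    randomised trials with a binary endpoint. Implements error-spending
    group-sequential designs (O'Brien-Fleming and Hwang-Shih-DeCani spending
    with binding futility via beta-spending, and Haybittle-Peto fixed
    boundaries) with a recursive-integration boundary solver, Bayesian
    posterior- and predictive-probability stopping rules under vague normal
    priors on each arm's log-odds, a trial simulation engine replicating the
    design assumptions of two large critical-care trials (ADRENAL and
    NICE-SUGAR), and an operating-characteristics module reporting type I
    error, power, early-decision probabilities, expected sample size and the
    bias of the treatment-effect estimate under early stopping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
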