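Package: sensbias
Title: Self-Evaluation Bias Decomposition Under Sequential Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how self-evaluations drift under sequential
    evaluative feedback. Implements an agent update model in which the
    sensitivity to feedback declines with self-evaluation, closed-form
    predictions of the resulting positive drift, a synthetic cohort
    generator reproducing a balanced alternating-feedback experimental
    protocol, regression-based estimation of sensitivity-to-feedback
    functions (ordinary least squares and participant-level mixed models),
    decomposition of the total self-evaluation bias into a self-enhancement
    component and a decreasing-sensitivity component, cluster-preserving
    bootstrap uncertainty, and bootstrap effect sizes. Includes a command
    line interface for simulation, analysis and validation runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
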