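Package: moralargs
Title: Moral Argument Theory of Opinion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how political discussion shapes moral
    opinions through the lens of the moral argument theory. Computes the
    HVFL (harm, violence, fairness, liberty) argument advantage of moral
    opinions from argument-endorsement judgments, simulates an agent-based
    opinion-dynamics model with heterogeneous discussion frequencies and
    ideological ingroup bias, prepares survey extracts (ANES/GSS style)
    for analysis, and estimates discussion-frequency effects with
    per-issue logistic models, pooled crossed random-intercept logistic
    models, and opinion-change-rate regressions. Includes a synthetic-data
    generator with known ground truth so the full pipeline is testable
    without external survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    sandwich,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
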