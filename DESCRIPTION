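Package: rewardbf
Title: Reward Responsiveness Under Brain Stimulation: Response Bias,
    Informed-Prior Bayes Factors and Design Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for probabilistic-reward-task studies of
    reward responsiveness under active versus sham prefrontal stimulation.
    Computes signal-detection response bias from trial-level task logs,
    scores PANAS and TEPS questionnaires with floor-effect detection,
    reduces factorial designs to one-degree-of-freedom effect summaries
    (paired differences, double-baselined mood indices, linear interaction
    contrasts, covariate-adjusted means), and evaluates those summaries
    with informed t-prior and default Cauchy (JZS) Bayes factors, a
    standard-error-scaling design analysis with a sequential stopping
    rule, and the complementary frequentist statistics (paired and
    one-sample t-tests, repeated-measures ANOVA/ANCOVA with sphericity
    handling). Includes a synthetic-study generator with a
    criterion-learning responder model and injectable stimulation
    effects, so the full pipeline is exercisable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
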