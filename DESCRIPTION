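Package: bwdce
Title: Design, Simulation, and Analysis of Best-Worst Discrete Choice
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for best-worst scaling (MaxDiff) discrete choice
    experiments on message testing: enumeration of attribute-level profiles
    under matching constraints, construction of pairwise-balanced 2-(v,k,1)
    choice-set designs with respondent blocking, a random-utility simulator
    for synthetic respondent panels with opt-out behaviour and a follow-up
    wave, best/worst coding of responses into a -1/0/+1 score, linear
    mixed-model estimation of effects-coded part-worth utilities with joint
    Wald tests and utility-range relative importance, and test-retest
    reliability via percent agreement, Cohen's kappa, and coefficient
    concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
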