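# bwdce

Design, simulation, and analysis of best-worst discrete choice experiments
(BWS / MaxDiff), built around the message-pretesting workflow used to select
smoking-cessation messages for cigarette package inserts: respondents see
sets of four candidate inserts — each a combination of a message *topic* and
a *imagery* type — and pick the one that would most and least motivate (or
help) them to quit, with an explicit "none would" opt-out per set.

The package is for researchers who design and analyse such experiments:

* **Design**: enumerate the meaningful topic x imagery profiles (with
  matching constraints for topics that only fit some images) and arrange the
  v profiles into `b = v(v-1)/12` choice sets of four such that every pair
  of profiles co-occurs in exactly one set (a 2-(v,4,1) pairwise balanced
  design), partitioned into respondent blocks.
* **Simulation**: a synthetic respondent panel (demographic margins,
  nicotine-dependence scores, an exact quit-intention quota) answering under
  a random-utility model — the (best, worst) pair in a set is drawn with
  probability proportional to `exp(U_best - U_worst)` — with covariate-driven
  opt-out and a follow-up wave of configurable consistency.
* **Estimation**: the alternative-level score (+1 best, -1 worst, 0
  otherwise, all 0 on opt-out sets) is regressed on effects-coded attribute
  levels by a linear mixed model with a respondent random intercept
  (`lme4`), controlling for block and respondent covariates. Part-worths
  per level (the sum-to-zero reference level recovered), joint Wald tests
  per attribute, imagery x sex / imagery x age / topic x imagery interaction
  models, and utility-range relative importance:
  `share_a = (max_l b_al - min_l b_al) / sum_a' range_a'`.
* **Reliability**: test-retest percent agreement and Cohen's kappa over the
  three-category code, coefficient-conclusion concordance across waves, and
  a built-in sweep showing the kappa paradox (high agreement, moderate
  kappa, when the 0 category dominates).

## Worked example

```r
library(bwdce)

topics <- attribute_spec("topic", c("improving lung health", "avoiding diabetes",
  "new disease", "enhancing wellbeing", "financial benefits"), "topic")
images <- attribute_spec("imagery", c("young man", "young woman", "older man",
  "older woman", "symbolic"), "imagery")
profiles <- enumerate_profiles(topics, images)        # 25 profiles
design <- build_pairwise_balanced_design(profiles, set_size = 4, seed = 42)
design <- partition_into_blocks(design, rep(5, 10), seed = 42)
design
#> <bw_design> 25 profiles, 50 choice sets of 4, 10 blocks (seed 42)
diag <- design_diagnostics(design)
diag$pair_coverage_ok                                 # TRUE: every pair once
unique(diag$profile_freq)                             # 8: each profile in 8 sets
```

Every profile pair co-occurs exactly once across the 50 sets and each
profile appears in exactly `(25-1)/(4-1) = 8` sets; each respondent block
carries 5 sets.

The utility-range importance calculation on the bundled reference
part-worths for the quitting-tips experiment:

```r
ref <- reference_partworths()
tips <- ref[ref$experiment == "dce2", ]
relative_importance_from_partworths(split(tips$estimate, tips$attribute))
#>   attribute range     share share_pct
#> 1   imagery 0.011 0.1486486        15
#> 2     topic 0.063 0.8513514        85
```

Topic drives 85% of choice variation, imagery 15%: the topic part-worths
span 0.063 (from -0.046 for the list-of-strategies message to +0.017 for
social support) while imagery spans only 0.011.

A full synthetic run — design, panel, two waves, coding, exclusion, mixed
models, importance, reliability — is one call:

```r
res <- run_pipeline(default_config(n = 300, seed = 1), models = "sex")
#> cohort: 300 respondents (150 quit-intenders)
#> dce1 baseline: 1500 records, analytic sample 234/300 (78%)
#> ...
#> dce1 reliability: agreement 0.950, kappa 0.915, concordance 0.90
render_importance_table(res$importance)
```

The per-stage messages report the analytic-sample fractions (respondents
who opted out of every set are excluded per experiment), and
`res$fits$dce1$baseline$main` holds the part-worth table with SEs,
Wald-z p-values, and per-attribute joint tests.

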