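---
title: "Methods: best-worst choice designs, simulation, and estimation in bwdce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: best-worst choice designs, simulation, and estimation in bwdce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwdce)
```

`bwdce` implements the full analysis chain for best-worst scaling (MaxDiff)
discrete choice experiments on two-attribute message stimuli: each
alternative is a (topic, imagery) combination, respondents mark the best and
worst alternative in sets of four, and may instead declare that none of the
alternatives would work for them. This vignette records the methods, the
modelling assumptions, and the design decisions taken where the methodology
leaves genuine freedom.

## Pairwise-balanced choice designs

"Alternatives pairwise independent across choice sets" is operationalized
as a 2-(v, k, 1) design: the `v` profiles are arranged into
`b = v(v-1)/(k(k-1))` sets of `k = 4` such that every unordered pair of
profiles co-occurs in exactly **one** set, whence every profile appears in
exactly `r = (v-1)/(k-1)` sets. For the two bundled design sizes this gives
`v = 25: b = 50, r = 8` and `v = 13: b = 13, r = 4`; the block-size
arithmetic (`50 x 6 = C(25,2)`, `13 x 6 = C(13,2)`) admits no other reading.
Infeasible `(v, k)` combinations (where `k-1` does not divide `v-1` or
`k(k-1)` does not divide `v(v-1)`) are rejected with an explicit error.

`build_pairwise_balanced_design()` is a seeded randomized search in two
stages:

1. **Hill-climbing pair cover.** Grow one set at a time from a random
   uncovered pair, preferring points all of whose pairs with the partial
   set are uncovered; when none exists, a *single* existing set may be
   evicted (its pairs return to the uncovered pool). Restarts on budget
   exhaustion. This solves `v = 13` (and sizes without algebraic structure,
   e.g. `v = 16`) in well under a second.
2. **Difference-family search.** For `v` prime (group `Z_v`) or `v = p^2`
   (group `Z_p x Z_p`) with `(v-1)/(k(k-1))` an integer, base blocks whose
   internal differences partition the nonzero group elements are found by a
   seeded randomized depth-first search over candidate blocks and developed
   by the `v` group translations. For `v = 25` there are 1280 valid base
   block pairs over `Z_5 x Z_5`, so the seeded search has genuine variety.

Pure stochastic search alone (greedy, single-eviction hill climbing,
simulated annealing, randomized backtracking) solves the 13-profile case
instantly but was not observed to complete the 25-profile case within large
budgets, which is why the algebraic second stage exists. A seeded random
relabeling of profiles and shuffle of set order is applied to either
stage's output, so designs vary with the seed and are byte-identical for a
fixed seed. `design_diagnostics()` verifies pair coverage by brute force.

**Blocking.** Sets are assigned to respondent blocks greedily in seeded
random order, each set going to the non-full block where its profiles are
currently least exposed (minimizing within-block exposure spread). Whether
the original ten-block layout was exposure-balanced is unknowable from the
published material; balancing is this package's choice. Within-set display
order randomization is left to presentation time and not encoded in the
design.

## The synthetic panel

`sample_cohort()` draws respondent characteristics independently from
fixed margins (age, sex, education, income, smoking frequency) matching a
Canadian adult-smoker online panel: 59% aged 40+, 58% female, 78% daily
smokers. Quit intention is filled by **exact quota** (default 50%), not by
independent draws. HSI (heaviness of smoking index, 0-6) is drawn from a
discrete distribution proportional to a normal density at the integer
scores with location and scale calibrated once (by Nelder-Mead) so the
discretized mean and SD hit 3.08 and 1.36. Education, income and smoking
margins whose published percentages do not total 100 (rounding) are
renormalized. Covariates are sampled independently; real panels have
correlated demographics, which the generator deliberately does not model.

## The response model

Latent attractiveness of alternative `j` for respondent `i`:

`U_ij = beta_topic(j) + beta_image(j) + gamma(topic_j, image_j) + s_i * delta_sex(image_j) + a_i * delta_age(image_j)`

with all part-worth vectors sum-to-zero (effects-coded), `s_i = +1/-1` for
male/female and `a_i = +1/-1` for ages 18-39/40-64. Conditional on
answering, the ordered (best, worst) pair is drawn with probability
proportional to `exp((U_b - U_w)/noise_scale)` over the `k(k-1)` ordered
pairs — the standard MaxDiff process model. The estimation side fits a
linear scoring model and is agnostic about the generative law; MaxDiff is
this package's choice of simulator, and parameter-recovery statements are
defined against it. Under it, the derivative of the expected -1/0/+1 score
with respect to a latent part-worth is about one half (at `k = 4`,
`noise_scale = 1`), so the default generative part-worths are set to twice
the bundled reference score-scale estimates to emulate effects of the
reference magnitude.

**Opt-out.** Each respondent x set opt-out is Bernoulli with logit
`intercept + b_qi * quit_intention + b_qa * quit_attempt + b_edu * education + b_inc * income + b_hsi * (HSI - 3) + u_i`,
education and income entering as centered level indices and `u_i` a
respondent random intercept. The default random-intercept SD is large (6.5
for the general-audience experiments, 5.5 for the reproductive-health one):
"no message would motivate me" behaves like a persistent respondent
attitude, nearly a latent class, rather than a per-set coin flip. The
intercepts were calibrated once, against the cohort margins, so that the
expected fraction of respondents opting out of *every* set they evaluate is
about 20%, 22% and 42% for the three bundled experiments — matching the
analytic-sample fractions (80%, 78%, 58%) these kinds of insert experiments
report — with opt-out more likely without quit intentions, with lower
education/income and with higher dependence (for the reproductive-health
experiment the quit-attempt sign is positive, mirroring its reversed
published exclusion pattern).

**Follow-up wave.** A configurable fraction of respondents (default 0.58)
is retained; each retained record is copied verbatim with probability
`theta` (default 0.9) and otherwise redrawn fresh from the same model.
Learning or wear-out across repeated exposure is explicitly not modelled.

## Coding and the analytic sample

The alternative-level score is +1 for the best choice, -1 for the worst, 0
otherwise; on an opt-out set all four alternatives score 0, so every set
contributes rows that sum to zero. Respondents who opted out of **all**
sets they evaluated in an experiment carry no information about the
alternatives and are excluded from that experiment's analysis; the 4-of-5
boundary stays in. Included and excluded groups are compared by Pearson
chi-square tests without continuity correction (the methodology names only
"chi-square tests"; categorical characteristics are kept as full
multi-category tables, not collapsed) and by a two-sample t-test for HSI,
since group HSI is reported as means.

## Estimation

Effects coding: an L-level attribute becomes L-1 columns, the last-listed
level is the reference (coded -1 throughout), and the reference part-worth
is recovered as minus the sum of the estimated ones, with a delta-method SE
from the coefficient covariance. Every reported part-worth vector therefore
sums to zero to machine precision.

The mixed linear model regresses the score on the effects columns with a
respondent random intercept, plus block-assignment fixed effects and the
respondent covariates. Block effects are included in all models (main and
interaction); the published material does not say whether interaction
models kept them, and including them is the safer control. REML is the
default, with an ML refit on non-convergence and ordinary least squares as
the degenerate-data fallback (constant response, unavailable covariance);
with zero random-intercept variance the mixed estimates coincide with OLS,
which the test suite checks exactly on small instances. p-values are
Wald-z; per-attribute joint tests are Wald chi-square on the L-1 free
coefficients (likelihood-ratio tests were considered and not made the
default, the estimator being REML).

Interaction models add one block at a time: imagery x sex and imagery x
dichotomized age (18-39 vs 40-64 — the cut follows the stimulus design,
where portrayed persons clearly look younger or older than 40) enter as
products of the imagery effects columns with the +1/-1 covariate, so
stratum part-worths are `b_image +/- b_interaction` and sum to zero within
stratum. Topic x imagery enters as all pairwise products of effects
columns; under matching constraints (13 observed cells but 16 cell
parameters) the aliased interaction columns are dropped and the joint test
runs on the estimable remainder, with estimated utilities reported for the
observed cells only.

**Relative importance.** `range_a = max_l b_al - min_l b_al`;
`share_a = range_a / sum(range)`. Shares are reported as proportions
(summing to exactly 1) and as whole percents rounded half away from zero.
On the bundled reference estimates this reproduces the quitting-tips
experiment's 85%/15% split exactly; for the other two experiments the
printed three-decimal coefficients yield 67%/33% and 36%/64% against
published 68%/32% and 38%/62% — the published figures were evidently
computed from unrounded coefficients, so the package asserts those two as
tolerance (±2 point) checks, not equalities.

## Reliability

The unit of test-retest agreement is the alternative-level three-category
code, matched on respondent x set x profile, restricted to respondents in
both waves (and, in the pipeline, to those in the analytic sample at both
waves). This per-alternative reading is the one under which a high raw
agreement coexists with a moderate kappa, because at least two of four
alternatives per answered set score 0; `kappa_prevalence_sweep()` makes the
dependence explicit by holding agreement fixed and growing the
middle-category prevalence. Coefficient concordance across waves counts a
coefficient as concordant when it is significant (alpha = 0.05) with the
same sign in both waves or non-significant in both; the coefficient
inventory compared is stated explicitly in the result rather than left
implicit.

## Numerical and testing notes

Degenerate inputs: an all-zero response yields all-zero part-worths with an
NA joint test (singular covariance); both raters constant on one category
makes kappa undefined (NA with a warning); an all-zero utility range makes
importance shares undefined (error). Ties in the block-assignment greedy
are broken by block index after a seeded shuffle of sets. All randomness
descends from one master seed through named substreams
(`substream_seed()`), so any stage can be re-run in isolation; two runs of
`run_pipeline()` under one config produce byte-identical artifacts.

The test suite exercises the design search at v = 4, 13, 16, 25; the
parameter-recovery study uses 200 replicates of 1000 respondents x 5 sets
of 4 (the scale the methodology targets), checking sign recovery for
part-worths of magnitude 0.05 and the size of the null-attribute joint
test; reliability properties use 120-500 respondents. The synthetic
cohort's covariate independence, the MaxDiff generative law, and the
absence of learning effects mean that passing tests demonstrate internal
statistical validity of the pipeline — not that any particular real panel
behaves like the simulator.

The package deliberately omits: D-efficient designs for conditional-logit
estimation, hierarchical-Bayes individual utilities, latent-class
segmentation, weighted kappa, survey weighting, and attrition models beyond
Bernoulli retention. A conditional-logit MaxDiff likelihood would be a
natural optional extra; the linear scoring model is the estimation target
here because it is what the insert-testing methodology prescribes.
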