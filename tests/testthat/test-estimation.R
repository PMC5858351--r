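simulate_coded <- function(design, model, n, experiment = "dce1", seed = 1,
                           cohort_seed = 2) {
  co <- small_cohort(n, design, experiment, seed = cohort_seed)
  recs <- simulate_choices(co, design, model, experiment = experiment,
                           seed = seed)
  fs <- filter_analytic_sample(recs)
  cw <- code_best_worst(recs, design)
  list(cohort = co, coded = cw[cw$respondent_id %in% fs$included, ])
}

test_that("with zero random-effect variance the fit equals least squares", {
  # one observation set per respondent: no repeated measures, so the random
  # intercept is estimated at (numerically) zero and fixed effects must
  # match OLS on the same matrix; instance kept at <= 50 rows
  d <- design13()
  co <- small_cohort(12, d, "dce3", seed = 4)
  recs <- data.frame(respondent_id = co$respondent_id, wave = "baseline",
                     experiment = "dce3",
                     set_id = rep_len(1:13, 12),
                     best_id = NA_integer_, worst_id = NA_integer_,
                     opted_out = FALSE)
  set.seed(99)
  for (i in seq_len(nrow(recs))) {
    S <- d$sets[[recs$set_id[i]]]
    bw <- sample(S, 2)
    recs$best_id[i] <- bw[1]; recs$worst_id[i] <- bw[2]
  }
  cw <- code_best_worst(recs, d)
  expect_lte(nrow(cw), 50L)
  fit <- fit_mixed_model(cw, co, d, "none", include_covariates = FALSE)
  mf <- bwdce:::build_model_frame(cw, co, d, "none", include_covariates = FALSE)
  ols <- lm(reformulate(mf$fixed, "y"), data = mf$data)
  keep <- intersect(names(fit$beta), names(coef(ols)))
  expect_equal(fit$beta[keep], coef(ols)[keep], tolerance = 1e-6)
})

test_that("an all-zero response yields all-zero part-worths", {
  d <- design13()
  co <- small_cohort(10, d, "dce3", seed = 4)
  recs <- simulate_choices(co, d, make_model(d, optout_intercept = 30),
                           experiment = "dce3", seed = 1)
  cw <- code_best_worst(recs, d)  # every y is 0 (filter bypassed on purpose)
  fit <- fit_mixed_model(cw, co, d, "none", include_covariates = FALSE)
  expect_true(all(abs(fit$partworths$estimate) < 1e-10))
})

test_that("part-worths sum to zero within each attribute in every fit", {
  d <- design13()
  tl <- unique(d$profiles$topic); il <- unique(d$profiles$imagery)
  m <- make_model(d, beta_topic = setNames(c(0.2, 0.1, -0.1, -0.2), tl),
                  beta_image = setNames(c(0.25, 0.05, -0.1, -0.2), il),
                  optout_intercept = -1.5, re_sd = 2)
  dat <- simulate_coded(d, m, 150, "dce3", seed = 3)
  for (ia in c("none", "sex", "age")) {
    fit <- fit_mixed_model(dat$coded, dat$cohort, d, ia)
    for (grp in split(fit$partworths, paste(fit$partworths$attribute,
                                            fit$partworths$stratum)))
      expect_lt(abs(sum(grp$estimate)), 1e-10)
  }
})

test_that("single-coefficient Wald chi-square equals the squared z statistic", {
  d <- design13()
  dat <- simulate_coded(d, make_model(d), 60, "dce3", seed = 5)
  fit <- fit_mixed_model(dat$coded, dat$cohort, d, "none")
  col <- fit$groups$topic$cols[1]
  w <- bwdce:::wald_test(fit$beta, fit$vcov, col, "one")
  z2 <- (fit$beta[[col]] / sqrt(fit$vcov[col, col]))^2
  expect_equal(w$statistic, z2, tolerance = 1e-10)
  expect_equal(w$df, 1L)
  # joint test accessor agrees with the stored table
  jt <- joint_attribute_test(fit, "topic")
  expect_equal(jt$statistic,
               fit$joint_tests$statistic[fit$joint_tests$term == "topic"],
               tolerance = 1e-10)
  expect_equal(jt$df, 3L)  # L - 1 free coefficients for 4 topic levels
})

test_that("strong part-worths are recovered with correct signs", {
  d <- design25()
  tl <- unique(d$profiles$topic); il <- unique(d$profiles$imagery)
  bt <- setNames(c(0.6, 0.3, 0, -0.3, -0.6), tl)
  bi <- setNames(c(0.4, 0.2, 0, -0.2, -0.4), il)
  m <- make_model(d, beta_topic = bt, beta_image = bi)
  dat <- simulate_coded(d, m, 400, "dce1", seed = 6)
  fit <- fit_mixed_model(dat$coded, dat$cohort, d, "none")
  pw <- fit$partworths
  est_t <- setNames(pw$estimate[pw$attribute == "topic"],
                    pw$level[pw$attribute == "topic"])
  expect_equal(sign(est_t[names(bt)[abs(bt) > 0]]),
               sign(bt[abs(bt) > 0]))
  expect_lt(fit$joint_tests$p[fit$joint_tests$term == "topic"], 1e-6)
})

test_that("a simulated sex-by-imagery interaction is detected and reported by stratum", {
  d <- design25()
  il <- unique(d$profiles$imagery)
  ds <- setNames(c(0.3, 0, 0, 0, -0.3), il)
  m <- make_model(d, delta_sex = ds)
  dat <- simulate_coded(d, m, 500, "dce1", seed = 7)
  fit <- fit_mixed_model(dat$coded, dat$cohort, d, "sex")
  pw <- fit$partworths
  expect_setequal(unique(pw$stratum), c("overall", "male", "female"))
  # within-stratum part-worths sum to zero
  for (st in c("male", "female"))
    expect_lt(abs(sum(pw$estimate[pw$stratum == st])), 1e-10)
  # male +1 coding: the delta shows up with opposite signs by stratum
  m1 <- pw[pw$stratum == "male" & pw$level == il[1], ]
  f1 <- pw[pw$stratum == "female" & pw$level == il[1], ]
  expect_gt(m1$estimate, f1$estimate)
  it <- fit$joint_tests[fit$joint_tests$term == "imagery:sex", ]
  expect_lt(it$p, 0.01)
  expect_equal(it$df, 4L)
})

test_that("topic-by-imagery fits work under matching constraints (aliased cells)", {
  d <- design13()
  tl <- unique(d$profiles$topic); il <- unique(d$profiles$imagery)
  u <- c(1.5, 0.5, -0.5, -1.5)
  gam <- outer(u, u) / max(abs(outer(u, u))) * 0.3
  dimnames(gam) <- list(tl, il)
  m <- make_model(d, beta_topic = setNames(c(0.2, 0, 0, -0.2), tl),
                  beta_image = setNames(c(0.2, 0, 0, -0.2), il), gamma = gam)
  dat <- simulate_coded(d, m, 200, "dce3", seed = 8)
  fit <- fit_mixed_model(dat$coded, dat$cohort, d, "topic_imagery")
  expect_equal(nrow(fit$cells), 13L)
  it <- fit$joint_tests[fit$joint_tests$term == "topic:imagery", ]
  expect_true(is.finite(it$statistic))
  expect_lte(it$df, 9L)  # aliased interaction columns are dropped
})

test_that("utility-range importance reproduces the reference worked examples", {
  ref <- reference_partworths()
  shares <- function(ex) {
    sub <- ref[ref$experiment == ex, ]
    out <- relative_importance_from_partworths(split(sub$estimate, sub$attribute))
    setNames(out$share_pct, out$attribute)
  }
  s2 <- shares("dce2")
  expect_equal(unname(s2["topic"]), 85)
  expect_equal(unname(s2["imagery"]), 15)
  s1 <- shares("dce1")
  expect_equal(unname(s1["topic"]), 67)
  expect_equal(unname(s1["imagery"]), 33)
  s3 <- shares("dce3")
  expect_equal(unname(s3["imagery"]), 64)
  expect_equal(unname(s3["topic"]), 36)
})

test_that("importance degenerate cases: single attribute, ties, all-zero", {
  one <- relative_importance_from_partworths(list(topic = c(-0.2, 0.2)))
  expect_equal(one$share_pct, 100)
  tie <- relative_importance_from_partworths(list(a = c(-1, 1), b = c(2, 4)))
  expect_equal(tie$share, c(0.5, 0.5))
  expect_error(relative_importance_from_partworths(list(a = c(0, 0))),
               "undefined")
  # unrounded shares always sum to exactly 1
  r <- relative_importance_from_partworths(list(a = c(-1, 1), b = c(0, 0.3),
                                                c = c(-0.2, 0.5)))
  expect_equal(sum(r$share), 1)
})
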