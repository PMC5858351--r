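test_that("record structure matches the cohort's block assignments", {
  d <- design13()
  co <- small_cohort(40, d, "dce3", seed = 2)
  m <- make_model(d)
  recs <- simulate_choices(co, d, m, experiment = "dce3", seed = 5)
  sets_per <- lengths(d$blocks)[co$block_dce3]
  expect_equal(nrow(recs), sum(sets_per))
  expect_true(all(recs$opted_out == (is.na(recs$best_id) & is.na(recs$worst_id))))
  act <- !recs$opted_out
  expect_true(all(recs$best_id[act] != recs$worst_id[act]))
  # chosen profiles belong to the record's set
  ok <- vapply(which(act), function(i)
    all(c(recs$best_id[i], recs$worst_id[i]) %in% d$sets[[recs$set_id[i]]]),
    logical(1))
  expect_true(all(ok))
})

test_that("equal utilities make every ordered (best, worst) pair equiprobable", {
  d <- design25()
  co <- small_cohort(1200, d, "dce1", seed = 3)
  recs <- simulate_choices(co, d, make_model(d), experiment = "dce1", seed = 4)
  # position of best within its set (1..4) should be uniform, same for worst
  pos_best <- mapply(function(s, b) match(b, d$sets[[s]]), recs$set_id, recs$best_id)
  pos_worst <- mapply(function(s, w) match(w, d$sets[[s]]), recs$set_id, recs$worst_id)
  pairs <- paste(pos_best, pos_worst)
  counts <- table(pairs)
  expect_length(counts, 12L)
  expected <- nrow(recs) / 12
  chi2 <- sum((counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, 11))
})

test_that("vanishing noise makes choices deterministic arg-max / arg-min", {
  d <- design13()
  co <- small_cohort(30, d, "dce3", seed = 2)
  tl <- unique(d$profiles$topic); il <- unique(d$profiles$imagery)
  bt <- setNames(c(0.9, 0.3, -0.4, -0.8), tl)
  bi <- setNames(c(0.21, 0.07, -0.11, -0.17), il)
  m <- make_model(d, beta_topic = bt, beta_image = bi, noise_scale = 1e-8)
  recs <- simulate_choices(co, d, m, experiment = "dce3", seed = 6)
  u <- setNames(bt[d$profiles$topic] + bi[d$profiles$imagery], d$profiles$profile_id)
  for (i in seq_len(nrow(recs))) {
    S <- as.character(d$sets[[recs$set_id[i]]])
    expect_equal(recs$best_id[i], as.integer(S[which.max(u[S])]))
    expect_equal(recs$worst_id[i], as.integer(S[which.min(u[S])]))
  }
})

test_that("opt-out extremes behave as limits", {
  d <- design13()
  co <- small_cohort(25, d, "dce3", seed = 2)
  none <- simulate_choices(co, d, make_model(d, optout_intercept = -30),
                           experiment = "dce3", seed = 7)
  expect_false(any(none$opted_out))
  all_out <- simulate_choices(co, d, make_model(d, optout_intercept = 30),
                              experiment = "dce3", seed = 7)
  expect_true(all(all_out$opted_out))
  expect_true(all(is.na(all_out$best_id)))
})

test_that("simulation is reproducible per seed", {
  d <- design13()
  co <- small_cohort(30, d, "dce3", seed = 2)
  m <- make_model(d, optout_intercept = -1, re_sd = 1)
  r1 <- simulate_choices(co, d, m, experiment = "dce3", seed = 11)
  r2 <- simulate_choices(co, d, m, experiment = "dce3", seed = 11)
  r3 <- simulate_choices(co, d, m, experiment = "dce3", seed = 12)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
})

test_that("theta = 1 follow-up copies the baseline for retained respondents", {
  d <- design13()
  co <- small_cohort(40, d, "dce3", seed = 2)
  m <- make_model(d)
  base <- simulate_choices(co, d, m, experiment = "dce3", seed = 5)
  fu <- simulate_followup(co, base, d, m, theta = 1, retention = 1, seed = 8)
  expect_equal(nrow(fu), nrow(base))
  expect_equal(fu$best_id, base$best_id)
  expect_equal(fu$worst_id, base$worst_id)
  expect_true(all(fu$wave == "followup"))
  expect_error(simulate_followup(co, base, d, m, theta = 1.2, retention = 1,
                                 seed = 8), "0, 1")
})

test_that("partial retention drops whole respondents", {
  d <- design13()
  co <- small_cohort(200, d, "dce3", seed = 2)
  m <- make_model(d)
  base <- simulate_choices(co, d, m, experiment = "dce3", seed = 5)
  fu <- simulate_followup(co, base, d, m, theta = 1, retention = 0.58, seed = 8)
  kept <- unique(fu$respondent_id)
  expect_lt(length(kept), 200L)
  expect_gt(length(kept), 60L)
  base_kept <- base[base$respondent_id %in% kept, ]
  expect_equal(nrow(fu), nrow(base_kept))
})

test_that("follow-up agreement matches the copy/redraw mixture expectation", {
  # flat utilities, no opt-out: an independent redraw agrees on a given
  # alternative's -1/0/+1 code with probability 1/16 + 1/4 + 1/16 = 0.375,
  # so per-cell agreement is theta + (1 - theta) * 0.375
  d <- design25()
  co <- small_cohort(500, d, "dce1", seed = 3)
  m <- make_model(d)
  theta <- 0.9
  base <- simulate_choices(co, d, m, experiment = "dce1", seed = 5)
  fu <- simulate_followup(co, base, d, m, theta = theta, retention = 1, seed = 9)
  cb <- code_best_worst(base, d)
  cf <- code_best_worst(fu, d)
  ag <- choice_agreement(cb, cf)
  expect_equal(ag$n_cells, nrow(cb))
  expect_lt(abs(ag$percent_agreement - (theta + (1 - theta) * 0.375)), 0.02)
})
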