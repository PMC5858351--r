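test_that("best/worst coding assigns +1/-1/0 and zeroes opt-out sets", {
  d <- design13()
  S <- d$sets[[1]]
  recs <- data.frame(respondent_id = c(1L, 2L), wave = "baseline",
                     experiment = "dce3", set_id = 1L,
                     best_id = c(S[1], NA), worst_id = c(S[3], NA),
                     opted_out = c(FALSE, TRUE))
  cw <- code_best_worst(recs, d)
  expect_equal(nrow(cw), 8L)
  r1 <- cw[cw$respondent_id == 1L, ]
  expect_equal(r1$y[match(S, r1$profile_id)], c(1L, 0L, -1L, 0L))
  expect_equal(cw$y[cw$respondent_id == 2L], rep(0L, 4))
  expect_equal(sum(r1$y), 0L)
  # labels resolved from the design
  expect_equal(r1$topic, d$profiles$topic[match(r1$profile_id,
                                                d$profiles$profile_id)])
})

test_that("coding validates record invariants", {
  d <- design13()
  S <- d$sets[[1]]
  bad_same <- data.frame(respondent_id = 1L, wave = "baseline",
                         experiment = "dce3", set_id = 1L,
                         best_id = S[1], worst_id = S[1], opted_out = FALSE)
  expect_error(code_best_worst(bad_same, d), "must differ")
  outside <- setdiff(d$profiles$profile_id, S)[1]
  bad_member <- data.frame(respondent_id = 1L, wave = "baseline",
                           experiment = "dce3", set_id = 1L,
                           best_id = outside, worst_id = S[2],
                           opted_out = FALSE)
  expect_error(code_best_worst(bad_member, d), "not among")
  bad_oo <- data.frame(respondent_id = 1L, wave = "baseline",
                       experiment = "dce3", set_id = 1L,
                       best_id = S[1], worst_id = S[2], opted_out = TRUE)
  expect_error(code_best_worst(bad_oo, d), "opted_out")
})

test_that("coding conserves counts: one +1 and one -1 per answered set", {
  d <- design25()
  co <- small_cohort(80, d, "dce1", seed = 2)
  m <- make_model(d, optout_intercept = -1, re_sd = 2)
  recs <- simulate_choices(co, d, m, experiment = "dce1", seed = 3)
  cw <- code_best_worst(recs, d)
  n_active <- sum(!recs$opted_out)
  expect_equal(sum(cw$y == 1L), n_active)
  expect_equal(sum(cw$y == -1L), n_active)
  sums <- tapply(cw$y, paste(cw$respondent_id, cw$set_id), sum)
  expect_true(all(sums == 0L))
})

test_that("analytic-sample filter excludes only all-set opt-outs and is idempotent", {
  d <- design13()
  mk <- function(id, oo) {
    S <- vapply(seq_along(oo), function(i) i, integer(1))
    data.frame(respondent_id = id, wave = "baseline", experiment = "dce3",
               set_id = seq_along(oo),
               best_id = ifelse(oo, NA, vapply(seq_along(oo), function(i)
                 d$sets[[i]][1], integer(1))),
               worst_id = ifelse(oo, NA, vapply(seq_along(oo), function(i)
                 d$sets[[i]][2], integer(1))),
               opted_out = oo)
  }
  recs <- rbind(mk(1L, rep(TRUE, 5)),        # opted out of 5/5 -> excluded
                mk(2L, c(TRUE, TRUE, TRUE, TRUE, FALSE)),  # 4/5 -> included
                mk(3L, rep(FALSE, 5)))
  fs <- filter_analytic_sample(recs)
  expect_equal(fs$excluded, 1L)
  expect_setequal(fs$included, c(2L, 3L))
  # idempotent: filtering the included records changes nothing
  fs2 <- filter_analytic_sample(recs[recs$respondent_id %in% fs$included, ])
  expect_equal(fs2$included, fs$included)
  expect_length(fs2$excluded, 0L)
})

test_that("no exclusions when opt-out is impossible", {
  d <- design13()
  co <- small_cohort(30, d, "dce3", seed = 2)
  recs <- simulate_choices(co, d, make_model(d, optout_intercept = -30),
                           experiment = "dce3", seed = 4)
  fs <- filter_analytic_sample(recs)
  expect_length(fs$excluded, 0L)
  expect_equal(fs$prop_excluded, 0)
})

test_that("exclusion comparison reproduces the Pearson chi-square and t tests", {
  co <- sample_cohort(200, seed = 3)
  inc <- co$respondent_id[1:120]; exc <- co$respondent_id[121:200]
  cmp <- compare_excluded(co, inc, exc)
  expect_true(all(c("chi-square", "t") %in% cmp$test))
  # cross-check one categorical test against the base-R oracle
  grp <- factor(ifelse(co$respondent_id %in% inc, "included", "excluded"),
                levels = c("included", "excluded"))
  oracle <- chisq.test(table(co$sex, grp), correct = FALSE)
  row <- cmp[cmp$characteristic == "sex", ]
  expect_equal(row$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(row$p, oracle$p.value, tolerance = 1e-12)
  orc_t <- t.test(co$hsi ~ grp)
  row_h <- cmp[cmp$characteristic == "hsi", ]
  expect_equal(row_h$statistic, unname(orc_t$statistic), tolerance = 1e-12)
  expect_error(compare_excluded(co, inc, integer(0)), "non-empty")
})

test_that("a constructed 2x2 split gives the hand-computed Pearson statistic", {
  # contingency table [[30,20],[70,80]]: expected [[25,25],[75,75]],
  # chi-square = 25/25 + 25/25 + 25/75 + 25/75 = 8/3
  x <- rep(c("a", "b"), times = c(50, 150))
  g <- c(rep(c("included", "excluded"), c(30, 20)),
         rep(c("included", "excluded"), c(70, 80)))
  tab <- table(x, g)
  ct <- chisq.test(tab, correct = FALSE)
  expect_equal(unname(ct$statistic), 8 / 3, tolerance = 1e-12)
  co <- sample_cohort(200, seed = 5)
  co$sex <- ifelse(x == "a", "male", "female")
  cmp <- compare_excluded(co, co$respondent_id[g == "included"],
                          co$respondent_id[g == "excluded"],
                          characteristics = "sex")
  expect_equal(cmp$statistic, 8 / 3, tolerance = 1e-12)
  expect_equal(cmp$df, 1)
})

test_that("identical group distributions give statistic 0 and p 1", {
  co <- sample_cohort(100, seed = 6)
  co$sex <- rep(c("male", "female"), 50)
  inc <- co$respondent_id[1:50]; exc <- co$respondent_id[51:100]
  # both halves have 25 male / 25 female
  cmp <- compare_excluded(co, inc, exc, characteristics = "sex")
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p, 1, tolerance = 1e-12)
})

test_that("effects coding follows the sum-to-zero convention", {
  lv <- paste0("L", 1:5)
  x <- effects_code(c("L1", "L5", "L3"), lv, prefix = "t_")
  expect_equal(dim(x), c(3L, 4L))
  expect_equal(unname(x[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(x[2, ]), c(-1, -1, -1, -1))
  expect_equal(unname(x[3, ]), c(0, 0, 1, 0))
  expect_error(effects_code("L9", lv), "unseen")
})

test_that("effects columns have mean zero on a balanced design", {
  d <- design25()
  # one record per choice set: every profile appears exactly r = 8 times
  recs <- data.frame(respondent_id = seq_along(d$sets), wave = "baseline",
                     experiment = "dce1", set_id = seq_along(d$sets),
                     best_id = vapply(d$sets, `[`, integer(1), 1L),
                     worst_id = vapply(d$sets, `[`, integer(1), 2L),
                     opted_out = FALSE)
  cw <- code_best_worst(recs, d)
  Xt <- effects_code(cw$topic, unique(d$profiles$topic), "t_")
  Xi <- effects_code(cw$imagery, unique(d$profiles$imagery), "i_")
  expect_true(all(abs(colMeans(Xt)) < 1e-12))
  expect_true(all(abs(colMeans(Xi)) < 1e-12))
})
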