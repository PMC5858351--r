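# Simulation of best/worst/opt-out responses under the random-utility model.

# Canonical level orders for the panel covariates (also the effects/index
# coding orders used by the opt-out model and the estimation module).
panel_levels <- function() {
  list(
    age_group = c("18-29", "30-39", "40-49", "50-64"),
    sex = c("male", "female"),
    education = c("high school or less", "college or some university",
                  "completed university or higher"),
    income = c("under $30,000", "$30,000-59,999", "$60,000-99,999",
               "$100,000 and over"),
    smoking_frequency = c("every day", "some days"),
    age_dichotomy = c("18-39", "40-64")
  )
}

# Opt-out linear predictor (excluding the random intercept): covariate
# indices are centered so the intercept is interpretable at the covariate
# midpoint.
optout_lp <- function(model, cov) {
  lv <- panel_levels()
  oo <- model$optout
  oo$intercept +
    oo$quit_intention * cov$quit_intention_6mo +
    oo$quit_attempt * cov$quit_attempt_4mo +
    oo$education * (match(cov$education, lv$education) - 2) +
    oo$income * (match(cov$income, lv$income) - 2.5) +
    oo$hsi * (cov$hsi - 3)
}

# Simulate responses for a given respondent x set frame. `frame` must have
# columns respondent_id, set_id; covariates are looked up in `cohort`.
simulate_records <- function(frame, cohort, design, model, experiment, wave, seed) {
  stopifnot(all(frame$respondent_id %in% cohort$respondent_id))
  prof <- design$profiles
  if (!setequal(unique(prof$topic), names(model$beta_topic)) ||
      !setequal(unique(prof$imagery), names(model$beta_image)))
    stop("model attribute levels do not match the design profiles", call. = FALSE)
  n <- nrow(frame)
  cov <- cohort[match(frame$respondent_id, cohort$respondent_id), ]
  base_u <- model$beta_topic[prof$topic] + model$beta_image[prof$imagery] +
    model$gamma[cbind(prof$topic, prof$imagery)]
  sex_sign <- ifelse(cov$sex == "male", 1, -1)
  age_sign <- ifelse(age_dichotomy(cov$age_group) == "18-39", 1, -1)
  k <- design$k
  # profile ids per record
  pid <- t(vapply(frame$set_id, function(s) design$sets[[s]], integer(k)))
  pidx <- matrix(match(pid, prof$profile_id), nrow = n)
  out <- with_seed(seed, {
    re <- stats::rnorm(length(unique(frame$respondent_id)), 0, model$optout$re_sd)
    names(re) <- as.character(unique(frame$respondent_id))
    p_out <- stats::plogis(optout_lp(model, cov) + re[as.character(frame$respondent_id)])
    opted <- stats::runif(n) < p_out
    U <- matrix(base_u[pidx], nrow = n) +
      sex_sign * matrix(model$delta_sex[prof$imagery[pidx]], nrow = n) +
      age_sign * matrix(model$delta_age[prof$imagery[pidx]], nrow = n)
    pairs <- expand.grid(b = seq_len(k), w = seq_len(k))
    pairs <- pairs[pairs$b != pairs$w, ]
    D <- (U[, pairs$b, drop = FALSE] - U[, pairs$w, drop = FALSE]) /
      model$noise_scale
    W <- exp(D - do.call(pmax, as.data.frame(D)))   # guard against overflow
    W <- W / rowSums(W)
    u <- stats::runif(n)
    cum <- t(apply(W, 1L, cumsum))
    pick <- rowSums(cum < u) + 1L
    pick[pick > nrow(pairs)] <- nrow(pairs)
    best <- pid[cbind(seq_len(n), pairs$b[pick])]
    worst <- pid[cbind(seq_len(n), pairs$w[pick])]
    best[opted] <- NA_integer_
    worst[opted] <- NA_integer_
    data.frame(respondent_id = frame$respondent_id, wave = wave,
               experiment = experiment, set_id = frame$set_id,
               best_id = best, worst_id = worst, opted_out = opted,
               stringsAsFactors = FALSE)
  })
  rownames(out) <- NULL
  out
}

#' Simulate best/worst/opt-out responses for a cohort
#'
#' For each respondent and each choice set in their assigned block: first
#' draw whether the respondent opts out of the set (logistic model with a
#' respondent random intercept); otherwise draw the (best, worst) pair with
#' probability proportional to `exp((U_best - U_worst)/noise_scale)` over
#' all ordered pairs of distinct alternatives.
#'
#' @param cohort data frame from [sample_cohort()] (must contain a
#'   `block_<experiment>` column).
#' @param design a blocked `bw_design` (see [partition_into_blocks()]).
#' @param model a `bw_utility_model`.
#' @param experiment experiment label, e.g. `"dce1"`.
#' @param wave wave label (`"baseline"` or `"followup"`).
#' @param seed integer seed.
#' @return A data frame of choice records: `respondent_id`, `wave`,
#'   `experiment`, `set_id`, `best_id`, `worst_id`, `opted_out`. `best_id`
#'   and `worst_id` are `NA` exactly when `opted_out` is `TRUE`.
#' @export
simulate_choices <- function(cohort, design, model, experiment = "dce1",
                             wave = "baseline", seed) {
  bcol <- paste0("block_", experiment)
  if (!bcol %in% names(cohort))
    stop("cohort has no block assignment column `", bcol, "`", call. = FALSE)
  if (is.null(design$blocks))
    stop("design has no blocks; call partition_into_blocks() first", call. = FALSE)
  nb <- length(design$blocks)
  if (any(cohort[[bcol]] < 1L | cohort[[bcol]] > nb))
    stop("cohort block assignments exceed the design's block count", call. = FALSE)
  sets_per_resp <- design$blocks[cohort[[bcol]]]
  frame <- data.frame(
    respondent_id = rep(cohort$respondent_id, lengths(sets_per_resp)),
    set_id = unlist(sets_per_resp)
  )
  simulate_records(frame, cohort, design, model, experiment, wave, seed)
}

#' Simulate a follow-up wave with imperfect consistency
#'
#' A configurable fraction of respondents is retained; each retained
#' baseline record is copied verbatim with probability `theta`
#' (`followup_consistency`) and otherwise replaced by a fresh draw from the
#' same random-utility model.
#'
#' @param cohort the cohort data frame.
#' @param baseline baseline records from [simulate_choices()].
#' @param design the blocked design the baseline was simulated from.
#' @param model the `bw_utility_model`.
#' @param theta copy probability; defaults to `model$followup_consistency`.
#' @param retention probability a respondent is re-contacted (default 0.58).
#' @param seed integer seed.
#' @return Follow-up records in the same format, `wave = "followup"`.
#' @export
simulate_followup <- function(cohort, baseline, design, model, theta = NULL,
                              retention = 0.58, seed) {
  theta <- theta %||% model$followup_consistency
  if (theta < 0 || theta > 1) stop("`theta` must be in [0, 1]", call. = FALSE)
  resp <- unique(baseline$respondent_id)
  experiment <- unique(baseline$experiment)
  stopifnot(length(experiment) == 1L)
  keep_draw <- with_seed(substream_seed(seed, "retention"), {
    kept <- resp[stats::runif(length(resp)) < retention]
    base <- baseline[baseline$respondent_id %in% kept, ]
    copy <- stats::runif(nrow(base)) < theta
    list(base = base, copy = copy)
  })
  base <- keep_draw$base; copy <- keep_draw$copy
  out <- base
  out$wave <- "followup"
  if (any(!copy)) {
    redraw <- simulate_records(base[!copy, c("respondent_id", "set_id")],
                               cohort, design, model, experiment,
                               wave = "followup",
                               seed = substream_seed(seed, "redraw"))
    out[!copy, ] <- redraw
  }
  rownames(out) <- NULL
  out
}
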