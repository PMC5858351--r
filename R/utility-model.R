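# Random-utility model driving the synthetic best/worst responses.

#' Specify a random-utility model for best-worst simulation
#'
#' The latent attractiveness of alternative j for respondent i is
#' `U_ij = beta_topic(j) + beta_image(j) + gamma(topic_j, image_j)
#'        + s_i * delta_sex(image_j) + a_i * delta_age(image_j)`
#' where `s_i` is +1 for males and -1 for females and `a_i` is +1 for ages
#' 18-39 and -1 for 40-64 (effects-coded covariates). Conditional on not
#' opting out, the (best, worst) pair in a choice set is drawn with
#' probability proportional to `exp((U_best - U_worst) / noise_scale)`
#' over all ordered pairs (the MaxDiff choice rule). Opting out of a set
#' follows a logistic model on quit intention, recent quit attempt,
#' education, income and HSI, with a respondent-level random intercept so
#' that all-set opt-outs arise naturally.
#'
#' @param beta_topic named sum-to-zero part-worth vector over topic levels.
#' @param beta_image named sum-to-zero part-worth vector over imagery levels.
#' @param gamma topic x imagery interaction matrix; every row and column must
#'   sum to zero. Defaults to no interaction.
#' @param delta_sex,delta_age sum-to-zero imagery modifier vectors applied
#'   with sign +1/-1 by respondent sex (male/female) and dichotomized age
#'   (18-39/40-64). Default zero.
#' @param noise_scale positive Gumbel-type scale of the choice noise; small
#'   values make choices nearly deterministic.
#' @param optout list with `intercept`, `quit_intention`, `quit_attempt`,
#'   `education`, `income`, `hsi`, `re_sd` (respondent random-intercept SD).
#'   Education and income enter as centered level indices, HSI centered at 3.
#' @param followup_consistency probability theta in \[0, 1\] that a follow-up
#'   response copies the baseline (best, worst, opt-out) triple.
#' @return An object of class `bw_utility_model`.
#' @export
utility_model <- function(beta_topic, beta_image, gamma = NULL,
                          delta_sex = NULL, delta_age = NULL,
                          noise_scale = 1,
                          optout = list(intercept = -20, quit_intention = 0,
                                        quit_attempt = 0, education = 0,
                                        income = 0, hsi = 0, re_sd = 0),
                          followup_consistency = 0.9) {
  chk0 <- function(x, what) {
    if (abs(sum(x)) > 1e-8)
      stop(sprintf("`%s` must sum to zero (effects coding)", what), call. = FALSE)
  }
  stopifnot(!is.null(names(beta_topic)), !is.null(names(beta_image)))
  chk0(beta_topic, "beta_topic"); chk0(beta_image, "beta_image")
  nt <- length(beta_topic); ni <- length(beta_image)
  if (is.null(gamma)) gamma <- matrix(0, nt, ni,
                                      dimnames = list(names(beta_topic), names(beta_image)))
  stopifnot(all(dim(gamma) == c(nt, ni)))
  if (any(abs(rowSums(gamma)) > 1e-8) || any(abs(colSums(gamma)) > 1e-8))
    stop("`gamma` must sum to zero over each margin", call. = FALSE)
  if (is.null(delta_sex)) delta_sex <- stats::setNames(numeric(ni), names(beta_image))
  if (is.null(delta_age)) delta_age <- stats::setNames(numeric(ni), names(beta_image))
  chk0(delta_sex, "delta_sex"); chk0(delta_age, "delta_age")
  if (noise_scale <= 0) stop("`noise_scale` must be positive", call. = FALSE)
  if (followup_consistency < 0 || followup_consistency > 1)
    stop("`followup_consistency` must be in [0, 1]", call. = FALSE)
  need <- c("intercept", "quit_intention", "quit_attempt", "education",
            "income", "hsi", "re_sd")
  miss <- setdiff(need, names(optout))
  if (length(miss)) stop("optout is missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  structure(list(beta_topic = beta_topic, beta_image = beta_image,
                 gamma = gamma, delta_sex = delta_sex, delta_age = delta_age,
                 noise_scale = noise_scale, optout = optout,
                 followup_consistency = followup_consistency),
            class = "bw_utility_model")
}

#' @export
print.bw_utility_model <- function(x, ...) {
  cat(sprintf("<bw_utility_model> %d topics x %d imagery, noise_scale %.3g, theta %.2f\n",
              length(x$beta_topic), length(x$beta_image), x$noise_scale,
              x$followup_consistency))
  invisible(x)
}

# Rank-1 sum-zero interaction pattern of a given peak magnitude, used by the
# default models to induce a topic x imagery interaction.
rank1_interaction <- function(topics, images, magnitude) {
  u <- seq_along(topics) - mean(seq_along(topics))
  w <- seq_along(images) - mean(seq_along(images))
  m <- outer(u, w)
  m <- m / max(abs(m)) * magnitude
  dimnames(m) <- list(topics, images)
  m
}

#' Default utility models for the three bundled experiments
#'
#' Generative part-worths are set to twice the reference score-scale
#' estimates of [reference_partworths()]: under the MaxDiff choice rule with
#' four alternatives the derivative of the expected -1/0/+1 score with
#' respect to a latent part-worth is about one half, so doubling reproduces
#' score-scale effects of the reference magnitude. A modest rank-1 topic x
#' imagery interaction and small sex/age imagery modifiers are included, and
#' the opt-out model is calibrated so that roughly 20% (`dce1`, `dce2`) or
#' 40% (`dce3`) of respondents opt out of every set they evaluate, more so
#' among respondents without quit intentions or recent quit attempts and
#' with lower education/income or higher dependence.
#'
#' @param experiment `"dce1"`, `"dce2"`, or `"dce3"`.
#' @return A `bw_utility_model`.
#' @export
default_utility_model <- function(experiment = c("dce1", "dce2", "dce3")) {
  experiment <- match.arg(experiment)
  ref <- reference_partworths()
  ref <- ref[ref$experiment == experiment, ]
  bt <- 2 * stats::setNames(ref$estimate[ref$attribute == "topic"],
                            ref$level[ref$attribute == "topic"])
  bi <- 2 * stats::setNames(ref$estimate[ref$attribute == "imagery"],
                            ref$level[ref$attribute == "imagery"])
  gam <- rank1_interaction(names(bt), names(bi),
                           if (experiment == "dce3") 0.15 else 0.04)
  ds <- stats::setNames(numeric(length(bi)), names(bi))
  da <- stats::setNames(numeric(length(bi)), names(bi))
  if (experiment == "dce1") {
    # males: symbolic up, older woman down; older smokers: young woman up,
    # older man down (reference-magnitude concordance effects, doubled)
    ds[c("older woman", "symbolic")] <- c(-0.024, 0.030)
    ds <- ds - mean(ds)
    da[c("young woman", "older man")] <- c(-0.026, 0.028)
    da <- da - mean(da)
  }
  if (experiment == "dce3") {
    ds[c("mom & dad with baby", "pregnant mom")] <- c(0.18, -0.06)
    ds <- ds - mean(ds)
  }
  oo <- switch(experiment,
    # the "no message would motivate/help me" trait is strongly bimodal: a
    # large respondent random intercept makes all-set opt-out a persistent
    # attitude rather than a per-set coin flip
    dce1 = list(intercept = -3.0, quit_intention = -0.8, quit_attempt = -0.6,
                education = -0.30, income = -0.20, hsi = 0.15, re_sd = 6.5),
    dce2 = list(intercept = -2.6, quit_intention = -0.8, quit_attempt = -0.6,
                education = -0.30, income = -0.20, hsi = 0.15, re_sd = 6.5),
    dce3 = list(intercept = 1.0, quit_intention = -0.7, quit_attempt = 0.6,
                education = -0.35, income = -0.25, hsi = 0.18, re_sd = 5.5))
  utility_model(beta_topic = bt, beta_image = bi, gamma = gam,
                delta_sex = ds, delta_age = da, noise_scale = 1,
                optout = oo, followup_consistency = 0.9)
}
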