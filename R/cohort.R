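# Synthetic respondent panel generation.

#' Default population margins for the simulated smoker panel
#'
#' Marginal distributions emulating an adult-smoker online panel: mostly 40+,
#' majority female, predominantly daily smokers, moderate nicotine
#' dependence. Values where the printed percentages do not sum to exactly
#' 100 (education, income, smoking frequency) are renormalized.
#'
#' @return A named list of probability vectors plus HSI moments and the quit
#'   attempt rate.
#' @export
default_margins <- function() {
  list(
    age_group = c("18-29" = 0.16, "30-39" = 0.25, "40-49" = 0.18, "50-64" = 0.41),
    sex = c(male = 0.42, female = 0.58),
    education = c("high school or less" = 33, "college or some university" = 37,
                  "completed university or higher" = 31) / 101,
    income = c("under $30,000" = 23, "$30,000-59,999" = 28,
               "$60,000-99,999" = 28, "$100,000 and over" = 17) / 96,
    smoking_frequency = c("every day" = 0.78, "some days" = 0.22),
    quit_attempt_4mo = 0.45,
    hsi_mean = 3.08, hsi_sd = 1.36
  )
}

# Discrete HSI distribution on 0..6: probabilities proportional to a normal
# density at the integer scores, with (mu, sigma) calibrated once so the
# discretized mean and SD match the targets.
hsi_distribution <- function(mean = 3.08, sd = 1.36) {
  obj <- function(par) {
    p <- stats::dnorm(0:6, par[1], exp(par[2])); p <- p / sum(p)
    m <- sum(0:6 * p); s <- sqrt(sum((0:6 - m)^2 * p))
    (m - mean)^2 + (s - sd)^2
  }
  par <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12))$par
  p <- stats::dnorm(0:6, par[1], exp(par[2]))
  p / sum(p)
}

#' Sample a synthetic respondent panel
#'
#' Respondent characteristics are independent categorical draws from the
#' supplied margins, except the quit-intention indicator, which is filled by
#' exact quota: `round(quota_quit_intention * n)` respondents intend to quit
#' within 6 months. HSI (heaviness of smoking index, 0-6) is drawn from a
#' discretized normal calibrated to the margin moments. Each respondent is
#' assigned uniformly to one choice-set block per experiment.
#'
#' @param n number of respondents.
#' @param margins list as returned by [default_margins()].
#' @param quota_quit_intention proportion of quit-intenders (exact quota).
#' @param n_blocks named integer vector: number of respondent blocks per
#'   experiment, e.g. `c(dce1 = 10, dce2 = 10, dce3 = 3)`.
#' @param seed integer seed.
#' @return A data frame with one row per respondent: `respondent_id`,
#'   `age_group`, `sex`, `education`, `income`, `smoking_frequency`, `hsi`,
#'   `quit_intention_6mo`, `quit_attempt_4mo`, and one `block_<experiment>`
#'   column per entry of `n_blocks`.
#' @examples
#' cohort <- sample_cohort(100, seed = 1)
#' table(cohort$quit_intention_6mo)  # exactly 50 TRUE
#' @export
sample_cohort <- function(n, margins = default_margins(),
                          quota_quit_intention = 0.5,
                          n_blocks = c(dce1 = 10L, dce2 = 10L, dce3 = 3L),
                          seed) {
  stopifnot(n >= 1L)
  for (m in c("age_group", "sex", "education", "income", "smoking_frequency")) {
    p <- margins[[m]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9)
      stop(sprintf("margin `%s` must be a probability vector summing to 1", m),
           call. = FALSE)
  }
  if (quota_quit_intention < 0 || quota_quit_intention > 1)
    stop("`quota_quit_intention` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    draw <- function(p) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
    out <- data.frame(
      respondent_id = seq_len(n),
      age_group = draw(margins$age_group),
      sex = draw(margins$sex),
      education = draw(margins$education),
      income = draw(margins$income),
      smoking_frequency = draw(margins$smoking_frequency),
      hsi = sample(0:6, n, replace = TRUE,
                   prob = hsi_distribution(margins$hsi_mean, margins$hsi_sd)),
      stringsAsFactors = FALSE
    )
    n_yes <- as.integer(round(quota_quit_intention * n))
    qi <- logical(n)
    qi[sample.int(n, n_yes)] <- TRUE
    out$quit_intention_6mo <- qi
    out$quit_attempt_4mo <- stats::runif(n) < margins$quit_attempt_4mo
    for (ex in names(n_blocks))
      out[[paste0("block_", ex)]] <- sample.int(n_blocks[[ex]], n, replace = TRUE)
    out
  })
}

# Dichotomized age used for age x imagery interaction models: the stimulus
# contrast is whether the person portrayed appears younger or older than 40.
age_dichotomy <- function(age_group) {
  ifelse(age_group %in% c("18-29", "30-39"), "18-39", "40-64")
}
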