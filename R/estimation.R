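# Linear mixed-model estimation of effects-coded part-worth utilities.
#
# The estimation target is a linear model of the alternative-level -1/0/+1
# best-worst score on effects-coded attribute levels, with a respondent
# random intercept for the repeated measures, block assignment and
# respondent covariates as fixed-effect controls. Coefficients are
# deviations from the grand mean; the reference level's part-worth is
# recovered as minus the sum of the estimated ones, with a delta-method SE.

# Assemble the model frame + named effect column groups for one experiment.
build_model_frame <- function(coded, cohort, design,
                              interaction = c("none", "sex", "age", "topic_imagery"),
                              include_covariates = TRUE) {
  interaction <- match.arg(interaction)
  lv <- panel_levels()
  experiment <- unique(coded$experiment)
  stopifnot(length(experiment) == 1L)
  tlev <- unique(design$profiles$topic)
  ilev <- unique(design$profiles$imagery)
  Xt <- effects_code(coded$topic, tlev, "topic_")
  Xi <- effects_code(coded$imagery, ilev, "imagery_")
  cov <- cohort[match(coded$respondent_id, cohort$respondent_id), ]
  dat <- data.frame(y = as.numeric(coded$y),
                    respondent = factor(coded$respondent_id))
  dat <- cbind(dat, Xt, Xi)
  groups <- list(topic = list(cols = colnames(Xt), levels = tlev),
                 imagery = list(cols = colnames(Xi), levels = ilev))
  int_cols <- character(0)
  if (interaction == "sex") {
    s <- ifelse(cov$sex == "male", 1, -1)
    Xint <- Xi * s
    colnames(Xint) <- sub("^imagery_", "sex_x_imagery_", colnames(Xi))
    dat <- cbind(dat, Xint); int_cols <- colnames(Xint)
  } else if (interaction == "age") {
    a <- ifelse(age_dichotomy(cov$age_group) == "18-39", 1, -1)
    Xint <- Xi * a
    colnames(Xint) <- sub("^imagery_", "age_x_imagery_", colnames(Xi))
    dat <- cbind(dat, Xint); int_cols <- colnames(Xint)
  } else if (interaction == "topic_imagery") {
    Xint <- do.call(cbind, lapply(seq_len(ncol(Xt)), function(i) {
      m <- Xt[, i] * Xi
      colnames(m) <- paste0("txi_", i, "_", seq_len(ncol(Xi)))
      m
    }))
    dat <- cbind(dat, Xint); int_cols <- colnames(Xint)
  }
  bcol <- paste0("block_", experiment)
  fixed <- c(groups$topic$cols, groups$imagery$cols, int_cols)
  if (bcol %in% names(cohort) && length(unique(cov[[bcol]])) > 1L) {
    dat$block <- factor(cov[[bcol]])
    fixed <- c(fixed, "block")
  }
  if (include_covariates) {
    dat$age_group <- factor(cov$age_group, levels = lv$age_group)
    dat$sex <- factor(cov$sex, levels = lv$sex)
    dat$education <- factor(cov$education, levels = lv$education)
    dat$income <- factor(cov$income, levels = lv$income)
    dat$smoking_frequency <- factor(cov$smoking_frequency,
                                    levels = lv$smoking_frequency)
    dat$hsi <- as.numeric(cov$hsi)
    dat$quit_intention_6mo <- as.numeric(cov$quit_intention_6mo)
    dat$quit_attempt_4mo <- as.numeric(cov$quit_attempt_4mo)
    covs <- c("age_group", "sex", "education", "income", "smoking_frequency",
              "hsi", "quit_intention_6mo", "quit_attempt_4mo")
    covs <- covs[vapply(covs, function(cn) {
      x <- dat[[cn]]; length(unique(as.character(x))) > 1L
    }, logical(1))]
    fixed <- c(fixed, covs)
  }
  list(data = dat, fixed = fixed, groups = groups, int_cols = int_cols,
       interaction = interaction, experiment = experiment)
}

# Sum / linear-combination part-worth recovery helper.
lincomb <- function(beta, V, w) {
  idx <- names(w)
  est <- sum(beta[idx] * w)
  se <- sqrt(max(0, t(w) %*% V[idx, idx, drop = FALSE] %*% w))
  c(estimate = est, se = se)
}

partworth_rows <- function(beta, V, cols, levels, attribute, stratum = "overall",
                           weight = NULL) {
  # weight: optional named multiplier on interaction columns appended to cols
  L <- length(levels)
  rows <- lapply(seq_len(L), function(l) {
    if (l < L) {
      w <- stats::setNames(numeric(length(cols)), cols)
      w[cols[l]] <- 1
      if (!is.null(weight)) w[names(weight)[l]] <- weight[[l]]
    } else {
      w <- stats::setNames(rep(-1, length(cols)), cols)
      if (!is.null(weight)) w[names(weight)] <- -unlist(weight)
    }
    w <- w[names(w) %in% names(beta)]
    est <- lincomb(beta, V, w)
    data.frame(attribute = attribute, stratum = stratum, level = levels[l],
               estimate = est[["estimate"]], se = est[["se"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$z <- out$estimate / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out
}

wald_test <- function(beta, V, cols, term) {
  cols <- cols[cols %in% names(beta)]
  if (!length(cols))
    return(data.frame(term = term, statistic = NA_real_, df = 0L, p = NA_real_))
  b <- beta[cols]
  Vb <- V[cols, cols, drop = FALSE]
  # a singular covariance block (degenerate fit) yields an NA test
  stat <- tryCatch(drop(t(b) %*% solve(Vb, b)),
                   error = function(e) NA_real_)
  df <- length(cols)
  data.frame(term = term, statistic = stat, df = df,
             p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fit the mixed linear model of best-worst scores
#'
#' Regresses the -1/0/+1 score on effects-coded topic and imagery levels
#' with a respondent random intercept (REML by default, maximum likelihood
#' as a fallback on non-convergence, ordinary least squares as a last
#' resort), controlling for block assignment and respondent covariates.
#' Optionally adds one interaction block: imagery x sex, imagery x
#' dichotomized age (18-39 vs 40-64), or topic x imagery.
#'
#' @param coded coded observations from [code_best_worst()], restricted to
#'   the analytic sample.
#' @param cohort the cohort data frame (covariate lookup).
#' @param design the `bw_design` (defines attribute level orders; the last
#'   level of each attribute is the effects-coding reference).
#' @param interaction `"none"` (main-effects model), `"sex"`, `"age"`, or
#'   `"topic_imagery"`.
#' @param include_covariates include sociodemographic and smoking covariates
#'   as fixed effects.
#' @param reml fit by REML (default) or ML.
#' @return An object of class `bw_fit`: `partworths` (per-level estimates,
#'   SEs and Wald-z p-values, including the recovered reference level;
#'   stratum-specific rows for interaction fits), `joint_tests` (per
#'   attribute and, if present, the interaction block), `cells` (estimated
#'   cell utilities for topic x imagery fits), and `meta`.
#' @export
fit_mixed_model <- function(coded, cohort, design,
                            interaction = c("none", "sex", "age", "topic_imagery"),
                            include_covariates = TRUE, reml = TRUE) {
  mf <- build_model_frame(coded, cohort, design, interaction, include_covariates)
  dat <- mf$data
  fml <- stats::reformulate(c(mf$fixed, "(1 | respondent)"), response = "y")
  estimator <- if (reml) "REML" else "ML"
  converged <- TRUE; singular <- FALSE
  fit <- tryCatch(
    suppressMessages(lme4::lmer(fml, data = dat, REML = reml,
                                control = lme4::lmerControl(calc.derivs = FALSE))),
    error = function(e) NULL)
  if (!is.null(fit) && reml && length(fit@optinfo$conv$lme4)) {
    refit <- tryCatch(
      suppressMessages(lme4::lmer(fml, data = dat, REML = FALSE,
                                  control = lme4::lmerControl(calc.derivs = FALSE))),
      error = function(e) NULL)
    if (!is.null(refit) && !length(refit@optinfo$conv$lme4)) {
      fit <- refit; estimator <- "ML"
    } else converged <- FALSE
  }
  ols_fallback <- function() {
    # degenerate data (e.g. constant response): ordinary least squares
    fml0 <- stats::reformulate(mf$fixed, response = "y")
    lmfit <- stats::lm(fml0, data = dat)
    beta <- stats::coef(lmfit)
    beta[is.na(beta)] <- 0
    V <- matrix(0, length(beta), length(beta),
                dimnames = list(names(beta), names(beta)))
    ok <- !is.na(stats::coef(lmfit))
    vc <- suppressWarnings(stats::vcov(lmfit))
    vc[!is.finite(vc)] <- 0
    V[ok, ok] <- vc
    list(beta = beta, V = V, estimator = "OLS",
         ll = as.numeric(stats::logLik(lmfit)), re_var = 0, singular = FALSE)
  }
  ext <- if (is.null(fit)) ols_fallback() else tryCatch({
    beta <- lme4::fixef(fit)
    V <- suppressWarnings(as.matrix(stats::vcov(fit)))
    if (anyNA(V)) stop("vcov unavailable")
    dimnames(V) <- list(names(beta), names(beta))
    list(beta = beta, V = V, estimator = estimator,
         ll = as.numeric(stats::logLik(fit)),
         re_var = unname(lme4::VarCorr(fit)$respondent[1L]),
         singular = lme4::isSingular(fit))
  }, error = function(e) ols_fallback())
  beta <- ext$beta; V <- ext$V; estimator <- ext$estimator
  ll <- ext$ll; re_var <- ext$re_var; singular <- ext$singular
  g <- mf$groups
  pw <- rbind(
    partworth_rows(beta, V, g$topic$cols, g$topic$levels, "topic"),
    partworth_rows(beta, V, g$imagery$cols, g$imagery$levels, "imagery")
  )
  jt <- rbind(wald_test(beta, V, g$topic$cols, "topic"),
              wald_test(beta, V, g$imagery$cols, "imagery"))
  cells <- NULL
  if (mf$interaction %in% c("sex", "age")) {
    strata <- if (mf$interaction == "sex") c("male", "female") else c("18-39", "40-64")
    ic <- mf$int_cols
    for (si in 1:2) {
      sgn <- c(1, -1)[si]
      wt <- stats::setNames(as.list(rep(sgn, length(ic))), ic)
      pw <- rbind(pw, partworth_rows(beta, V, g$imagery$cols, g$imagery$levels,
                                     "imagery", stratum = strata[si], weight = wt))
    }
    jt <- rbind(jt, wald_test(beta, V, ic, paste0("imagery:", mf$interaction)))
  } else if (mf$interaction == "topic_imagery") {
    jt <- rbind(jt, wald_test(beta, V, mf$int_cols, "topic:imagery"))
    cells <- interaction_cells(beta, V, mf, design)
  }
  structure(list(partworths = pw, joint_tests = jt, cells = cells,
                 beta = beta, vcov = V, groups = g, int_cols = mf$int_cols,
                 interaction = mf$interaction,
                 meta = list(experiment = mf$experiment,
                             n_respondents = length(unique(coded$respondent_id)),
                             n_rows = nrow(dat), estimator = estimator,
                             converged = converged, singular = singular,
                             loglik = ll, re_var = re_var)),
            class = "bw_fit")
}

# Estimated utility deviation of each observed (topic, imagery) cell under a
# topic x imagery interaction fit; aliased interaction columns (possible when
# matching constraints leave fewer cells than parameters) contribute zero.
interaction_cells <- function(beta, V, mf, design) {
  g <- mf$groups
  tlev <- g$topic$levels; ilev <- g$imagery$levels
  Lt <- length(tlev); Li <- length(ilev)
  eff <- function(l, L) { e <- numeric(L - 1L); if (l < L) e[l] <- 1 else e[] <- -1; e }
  cells <- unique(design$profiles[, c("topic", "imagery")])
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    ti <- match(cells$topic[r], tlev); ii <- match(cells$imagery[r], ilev)
    et <- eff(ti, Lt); ei <- eff(ii, Li)
    w <- c(stats::setNames(et, g$topic$cols), stats::setNames(ei, g$imagery$cols))
    for (i in seq_len(Lt - 1L)) for (j in seq_len(Li - 1L))
      w[paste0("txi_", i, "_", j)] <- et[i] * ei[j]
    w <- w[names(w) %in% names(beta)]
    est <- lincomb(beta, V, w)
    data.frame(topic = cells$topic[r], imagery = cells$imagery[r],
               estimate = est[["estimate"]], se = est[["se"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$z <- out$estimate / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out
}

#' @export
print.bw_fit <- function(x, ...) {
  cat(sprintf("<bw_fit> %s | %s | %d respondents, %d rows (%s%s)\n",
              x$meta$experiment, x$interaction, x$meta$n_respondents,
              x$meta$n_rows, x$meta$estimator,
              if (x$meta$singular) ", singular RE" else ""))
  print(x$partworths, digits = 3)
  cat("\nJoint Wald tests:\n")
  print(x$joint_tests, digits = 4)
  invisible(x)
}

#' Joint Wald test for an attribute's part-worths
#'
#' Chi-square test that all L-1 free effects-coded coefficients of the
#' attribute are zero, using their estimated covariance; `df = L - 1`. For a
#' fitted interaction block, use the term name shown in `fit$joint_tests`.
#'
#' @param fit a `bw_fit`.
#' @param attribute `"topic"`, `"imagery"`, or an interaction term name.
#' @return A one-row data frame: `term`, `statistic`, `df`, `p`.
#' @export
joint_attribute_test <- function(fit, attribute) {
  stopifnot(inherits(fit, "bw_fit"))
  cols <- if (attribute %in% names(fit$groups)) fit$groups[[attribute]]$cols
          else if (length(fit$int_cols) &&
                   attribute %in% fit$joint_tests$term) fit$int_cols
          else stop("unknown attribute: ", attribute, call. = FALSE)
  wald_test(fit$beta, fit$vcov, cols, attribute)
}

#' Utility-range relative importance of the attributes
#'
#' An attribute's utility range is the difference between its highest and
#' lowest estimated part-worth (reference level included); its relative
#' importance is that range divided by the sum of all attributes' ranges.
#' Reported percentages are rounded to the nearest whole percent, halves
#' away from zero.
#'
#' @param fit a `bw_fit` (the overall part-worths are used).
#' @return A data frame: `attribute`, `range`, `share` (proportion), and
#'   `share_pct` (rounded whole percent). Shares sum to exactly 1 before
#'   rounding. All ranges zero is flagged as an error.
#' @export
relative_importance <- function(fit) {
  stopifnot(inherits(fit, "bw_fit"))
  pw <- fit$partworths[fit$partworths$stratum == "overall", ]
  parts <- split(pw$estimate, pw$attribute)
  relative_importance_from_partworths(parts)
}

#' Utility-range relative importance from raw part-worth vectors
#'
#' The regression-free form of [relative_importance()], applicable to any
#' table of per-level part-worths (for instance the bundled
#' [reference_partworths()] estimates).
#'
#' @param partworths named list of numeric part-worth vectors, one per
#'   attribute (full level sets, reference included).
#' @return A data frame: `attribute`, `range`, `share`, `share_pct`.
#' @examples
#' ref <- reference_partworths()
#' tips <- ref[ref$experiment == "dce2", ]
#' relative_importance_from_partworths(
#'   split(tips$estimate, tips$attribute))  # topic 85%, imagery 15%
#' @export
relative_importance_from_partworths <- function(partworths) {
  stopifnot(is.list(partworths), length(partworths) >= 1L)
  rng <- vapply(partworths, function(b) max(b) - min(b), numeric(1))
  if (all(rng == 0))
    stop("all utility ranges are zero; importance shares are undefined",
         call. = FALSE)
  share <- rng / sum(rng)
  data.frame(attribute = names(rng), range = unname(rng),
             share = unname(share),
             share_pct = unname(round_half_away(100 * share)),
             stringsAsFactors = FALSE)
}
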