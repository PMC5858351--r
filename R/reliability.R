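# Test-retest reliability of choices and of analytic conclusions.

#' Cohen's kappa for two categorical vectors
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` where `p_o`
#' is the observed agreement proportion and `p_e` the agreement expected
#' from the two raters' marginal category frequencies. When `p_e = 1` (both
#' raters constant on the same category) kappa is undefined and `NA` is
#' returned with a warning.
#'
#' @param x,y equal-length vectors of category codes.
#' @param categories category set (default: union of observed values).
#' @return A list with `kappa`, `p_o`, `p_e`, and the cross-table `table`.
#' @export
cohen_kappa <- function(x, y, categories = NULL) {
  stopifnot(length(x) == length(y), length(x) > 0L)
  if (is.null(categories)) categories <- sort(unique(c(x, y)))
  x <- factor(x, levels = categories)
  y <- factor(y, levels = categories)
  tab <- table(x, y)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps^0.5) {
    warning("expected agreement is 1; kappa undefined")
    kap <- NA_real_
  } else kap <- (p_o - p_e) / (1 - p_e)
  list(kappa = kap, p_o = p_o, p_e = p_e, table = tab)
}

#' Test-retest agreement of best-worst choices
#'
#' Compares the alternative-level -1/0/+1 codes across two waves, matched on
#' respondent x set x profile cells. Only respondents present in both waves
#' contribute; cells missing in either wave are dropped. Returns the raw
#' percent agreement and Cohen's kappa over the three-category code. Because
#' two of the four alternatives in every answered set score 0 (and opt-out
#' sets score all 0), raw agreement can be high while kappa stays moderate
#' -- the classic kappa paradox.
#'
#' @param coded_baseline,coded_followup coded observations from
#'   [code_best_worst()] for the two waves (one experiment).
#' @return A list: `percent_agreement`, `kappa`, `p_e`, `n_cells`, `table`.
#' @export
choice_agreement <- function(coded_baseline, coded_followup) {
  key <- function(d) paste(d$respondent_id, d$set_id, d$profile_id, sep = "/")
  both <- intersect(unique(coded_baseline$respondent_id),
                    unique(coded_followup$respondent_id))
  b <- coded_baseline[coded_baseline$respondent_id %in% both, ]
  f <- coded_followup[coded_followup$respondent_id %in% both, ]
  m <- match(key(b), key(f))
  ok <- !is.na(m)
  if (!any(ok)) stop("no overlapping respondent x set x profile cells",
                     call. = FALSE)
  kk <- cohen_kappa(b$y[ok], f$y[m[ok]], categories = c(-1L, 0L, 1L))
  list(percent_agreement = kk$p_o, kappa = kk$kappa, p_e = kk$p_e,
       n_cells = sum(ok), table = kk$table)
}

#' Concordance of coefficient conclusions across waves
#'
#' A coefficient leads to the same conclusion in both waves when it is
#' significant at the 0.05 level with the same sign in both, or
#' non-significant in both. Coefficients are matched on (attribute, stratum,
#' level) across the two fits.
#'
#' @param fit_baseline,fit_followup `bw_fit` objects with matching model
#'   specifications.
#' @param alpha significance threshold (default 0.05).
#' @return A list: `concordance` (fraction concordant), `n_compared`,
#'   `discordant` (data frame of mismatching coefficients), `detail`.
#' @export
coefficient_concordance <- function(fit_baseline, fit_followup, alpha = 0.05) {
  stopifnot(inherits(fit_baseline, "bw_fit"), inherits(fit_followup, "bw_fit"))
  kb <- fit_baseline$partworths
  kf <- fit_followup$partworths
  keyb <- paste(kb$attribute, kb$stratum, kb$level, sep = "/")
  keyf <- paste(kf$attribute, kf$stratum, kf$level, sep = "/")
  if (!setequal(keyb, keyf))
    stop("the two fits report different coefficient sets", call. = FALSE)
  m <- match(keyb, keyf)
  concl <- function(est, p) ifelse(p < alpha, ifelse(est > 0, "sig+", "sig-"), "ns")
  cb <- concl(kb$estimate, kb$p)
  cf <- concl(kf$estimate[m], kf$p[m])
  agree <- cb == cf
  detail <- data.frame(attribute = kb$attribute, stratum = kb$stratum,
                       level = kb$level, baseline = cb, followup = cf,
                       concordant = agree, stringsAsFactors = FALSE)
  list(concordance = mean(agree), n_compared = length(agree),
       discordant = detail[!agree, , drop = FALSE], detail = detail)
}

#' Kappa-paradox sweep: kappa vs middle-category prevalence
#'
#' Holds the observed agreement fixed and computes Cohen's kappa as the
#' prevalence of the dominant middle (0) category grows, splitting the
#' remainder evenly between -1 and +1 on both margins. Demonstrates how a
#' high raw agreement coexists with a moderate kappa when one category
#' dominates.
#'
#' @param p_o fixed observed agreement (default 0.94).
#' @param pi0 vector of middle-category prevalences.
#' @return A data frame: `pi0`, `p_e`, `kappa` (NA where `p_e >= p_o` is
#'   infeasible is retained as the algebraic value; NA only when `p_e = 1`).
#' @export
kappa_prevalence_sweep <- function(p_o = 0.94, pi0 = seq(0.34, 0.96, by = 0.02)) {
  stopifnot(p_o > 0, p_o <= 1, all(pi0 >= 0), all(pi0 < 1))
  p_e <- pi0^2 + 2 * ((1 - pi0) / 2)^2
  kappa <- ifelse(1 - p_e < .Machine$double.eps^0.5, NA_real_,
                  (p_o - p_e) / (1 - p_e))
  data.frame(pi0 = pi0, p_e = p_e, kappa = kappa)
}
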