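# Best/worst coding, analytic-sample filtering, and effects coding.

#' Code best/worst records into the alternative-level -1/0/+1 score
#'
#' Expands each choice record to one row per alternative in the set. The
#' alternative chosen as best scores +1, the one chosen as worst scores -1,
#' the remaining alternatives 0. When the respondent opted out of the set,
#' every alternative in it scores 0.
#'
#' @param records choice records (see [simulate_choices()] for the schema).
#' @param design the `bw_design` the records refer to.
#' @return A data frame with one row per alternative: the record keys plus
#'   `profile_id`, `topic`, `imagery`, and the score `y`.
#' @export
code_best_worst <- function(records, design) {
  prof <- design$profiles
  k <- design$k
  n <- nrow(records)
  pid <- t(vapply(records$set_id, function(s) design$sets[[s]], integer(k)))
  # validate the record invariants against the design
  bad_oo <- records$opted_out != (is.na(records$best_id) & is.na(records$worst_id))
  if (any(bad_oo))
    stop("opted_out must coincide with missing best/worst", call. = FALSE)
  act <- !records$opted_out
  if (any(records$best_id[act] == records$worst_id[act]))
    stop("best and worst must differ within a choice set", call. = FALSE)
  if (any(rowSums(pid[act, , drop = FALSE] == records$best_id[act]) != 1L) ||
      any(rowSums(pid[act, , drop = FALSE] == records$worst_id[act]) != 1L))
    stop("best/worst profile not among the set's alternatives", call. = FALSE)
  long <- records[rep(seq_len(n), each = k),
                  c("respondent_id", "wave", "experiment", "set_id", "opted_out")]
  long$profile_id <- as.vector(t(pid))
  long$y <- 0L
  long$y[long$profile_id == rep(records$best_id, each = k) & !long$opted_out] <- 1L
  long$y[long$profile_id == rep(records$worst_id, each = k) & !long$opted_out] <- -1L
  m <- match(long$profile_id, prof$profile_id)
  long$topic <- prof$topic[m]
  long$imagery <- prof$imagery[m]
  rownames(long) <- NULL
  long
}

#' Apply the analytic-sample exclusion rule
#'
#' Respondents who opted out of every choice set they evaluated in an
#' experiment contribute no information about the alternatives and are
#' excluded from that experiment's analysis. Exclusion is per experiment.
#'
#' @param records choice records for one experiment.
#' @return A list with `included` and `excluded` respondent id vectors and
#'   the exclusion fraction `prop_excluded`. Filtering is idempotent:
#'   applying it to the records of included respondents changes nothing.
#' @export
filter_analytic_sample <- function(records) {
  if (!nrow(records)) stop("no records supplied", call. = FALSE)
  stopifnot(length(unique(records$experiment)) == 1L)
  all_out <- tapply(records$opted_out, records$respondent_id, all)
  ids <- as.integer(names(all_out))
  list(included = ids[!all_out], excluded = ids[all_out],
       prop_excluded = mean(all_out))
}

#' Compare included vs excluded respondents
#'
#' Pearson chi-square tests (no continuity correction) on each categorical
#' characteristic, and a two-sample t-test on HSI, between the analytic
#' sample and the respondents excluded for opting out of every set.
#'
#' @param cohort the cohort data frame.
#' @param included,excluded respondent id vectors from
#'   [filter_analytic_sample()].
#' @param characteristics character vector of cohort columns to compare.
#' @return A data frame with one row per characteristic: `test`
#'   (`"chi-square"` or `"t"`), `statistic`, `df`, `p`, and `note`
#'   (`"unavailable"` when a zero expected count makes the test invalid).
#' @export
compare_excluded <- function(cohort, included, excluded,
                             characteristics = c("age_group", "sex", "education",
                                                 "income", "smoking_frequency",
                                                 "hsi", "quit_intention_6mo",
                                                 "quit_attempt_4mo")) {
  if (!length(included) || !length(excluded))
    stop("both groups must be non-empty", call. = FALSE)
  grp <- factor(ifelse(cohort$respondent_id %in% included, "included", "excluded"),
                levels = c("included", "excluded"))
  keep <- cohort$respondent_id %in% c(included, excluded)
  out <- lapply(characteristics, function(ch) {
    x <- cohort[[ch]][keep]; g <- grp[keep]
    if (is.numeric(x) && length(unique(x)) > 7L || ch == "hsi") {
      tt <- stats::t.test(x ~ g)
      data.frame(characteristic = ch, test = "t",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, note = "", stringsAsFactors = FALSE)
    } else {
      tab <- table(x, g)
      exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_cnt == 0))
        return(data.frame(characteristic = ch, test = "chi-square",
                          statistic = NA_real_, df = NA_real_, p = NA_real_,
                          note = "unavailable", stringsAsFactors = FALSE))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(characteristic = ch, test = "chi-square",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Effects-code a categorical variable
#'
#' Sum-to-zero coding: an L-level attribute becomes L-1 indicator-style
#' columns; level `l < L` scores 1 on its own column, the last (reference)
#' level scores -1 on every column. Coefficients then measure deviations
#' from the grand mean, and the reference part-worth is recovered as minus
#' the sum of the estimated ones.
#'
#' @param x character or factor vector of observed levels.
#' @param levels level order; the last entry is the reference.
#' @param prefix column-name prefix.
#' @return A numeric matrix with `length(levels) - 1` columns.
#' @export
effects_code <- function(x, levels, prefix = "eff") {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop("unseen level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  L <- length(levels)
  m <- matrix(0, length(x), L - 1L,
              dimnames = list(NULL, paste0(prefix, seq_len(L - 1L))))
  for (l in seq_len(L - 1L)) m[x == levels[l], l] <- 1
  m[x == levels[L], ] <- -1
  m
}
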