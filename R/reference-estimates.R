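# Reference part-worth estimates used in worked examples.

#' Reference part-worth estimates for three insert-message experiments
#'
#' Published main-effect part-worth utilities (with standard errors) from a
#' best-worst choice study of smoking-cessation messages for cigarette pack
#' inserts: `dce1` tested five cessation-benefit topics against five imagery
#' types, `dce2` five quitting-tips topics against the same imagery types,
#' and `dce3` four reproductive-health topics against four imagery types.
#' Estimates are on the -1/0/+1 best-worst score scale and are effects
#' coded, so each attribute's part-worths sum to zero. They serve as the
#' worked example for [relative_importance_from_partworths()] and as
#' magnitude calibration for the synthetic utility models.
#'
#' @return A data frame with columns `experiment`, `attribute`, `level`,
#'   `estimate`, `se`.
#' @export
reference_partworths <- function() {
  rows <- list(
    c("dce1", "topic", "improving lung health", 0.000, 0.004),
    c("dce1", "topic", "avoiding diabetes", 0.014, 0.004),
    c("dce1", "topic", "new disease", 0.015, 0.004),
    c("dce1", "topic", "enhancing wellbeing", -0.013, 0.004),
    c("dce1", "topic", "financial benefits", -0.016, 0.004),
    c("dce1", "imagery", "young man", -0.007, 0.004),
    c("dce1", "imagery", "young woman", 0.008, 0.004),
    c("dce1", "imagery", "older man", -0.005, 0.004),
    c("dce1", "imagery", "older woman", -0.001, 0.004),
    c("dce1", "imagery", "symbolic", 0.005, 0.004),
    c("dce2", "topic", "stress reduction", 0.013, 0.004),
    c("dce2", "topic", "list of cessation strategies", -0.046, 0.004),
    c("dce2", "topic", "nicotine replacement therapy", 0.011, 0.004),
    c("dce2", "topic", "social support", 0.017, 0.005),
    c("dce2", "topic", "physical activity", 0.005, 0.004),
    c("dce2", "imagery", "young man", -0.006, 0.004),
    c("dce2", "imagery", "young woman", 0.003, 0.004),
    c("dce2", "imagery", "older man", 0.003, 0.004),
    c("dce2", "imagery", "older woman", -0.005, 0.004),
    c("dce2", "imagery", "symbolic", 0.005, 0.004),
    c("dce3", "topic", "health of mom & baby", 0.093, 0.012),
    c("dce3", "topic", "health of mom & baby + quit tips", -0.006, 0.013),
    c("dce3", "topic", "health of mom, dad & baby", 0.031, 0.013),
    c("dce3", "topic", "fertility & healthy pregnancy", -0.118, 0.011),
    c("dce3", "imagery", "pregnant mom", 0.023, 0.013),
    c("dce3", "imagery", "mom with baby", 0.107, 0.011),
    c("dce3", "imagery", "mom & dad with baby", 0.122, 0.015),
    c("dce3", "imagery", "symbolic (pregnant mom)", -0.252, 0.011)
  )
  out <- data.frame(
    experiment = vapply(rows, `[`, character(1), 1L),
    attribute = vapply(rows, `[`, character(1), 2L),
    level = vapply(rows, `[`, character(1), 3L),
    estimate = as.numeric(vapply(rows, `[`, character(1), 4L)),
    se = as.numeric(vapply(rows, `[`, character(1), 5L)),
    stringsAsFactors = FALSE
  )
  out
}
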