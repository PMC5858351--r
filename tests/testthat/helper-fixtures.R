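# Shared fixtures, built in code at test time.

topics5 <- function() attribute_spec("topic", paste0("topic", 1:5), "topic")
images5 <- function() attribute_spec("imagery", paste0("image", 1:5), "imagery")
topics4 <- function() attribute_spec("topic", paste0("topic", 1:4), "topic")
images4 <- function() attribute_spec("imagery", paste0("image", 1:4), "imagery")

# matching constraint with one topic fitting all four images and the other
# three topics fitting three each (13 allowed combinations)
dce3_match <- function() {
  m <- matrix(TRUE, 4, 4)
  m[2, 3] <- FALSE; m[3, 1] <- FALSE; m[4, 2] <- FALSE
  match_matrix(topics4(), images4(), m)
}

design25 <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      d <- build_pairwise_balanced_design(
        enumerate_profiles(topics5(), images5()), 4, seed = seed)
      cache <<- partition_into_blocks(d, rep(5L, 10L), seed = seed)
    }
    cache
  }
})

design13 <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      d <- build_pairwise_balanced_design(
        enumerate_profiles(topics4(), images4(), dce3_match()), 4, seed = seed)
      cache <<- partition_into_blocks(d, c(5L, 4L, 4L), seed = seed)
    }
    cache
  }
})

# cohort sized for a design's block count
small_cohort <- function(n, design, experiment = "dce1", seed = 1) {
  nb <- stats::setNames(length(design$blocks), experiment)
  sample_cohort(n, n_blocks = nb, seed = seed)
}

# utility model over a design's levels with given part-worths; opt-out off
# by default (intercept -20, no heterogeneity)
make_model <- function(design, beta_topic = NULL, beta_image = NULL,
                       noise_scale = 1, optout_intercept = -20, re_sd = 0,
                       ...) {
  tl <- unique(design$profiles$topic)
  il <- unique(design$profiles$imagery)
  if (is.null(beta_topic)) beta_topic <- stats::setNames(numeric(length(tl)), tl)
  if (is.null(beta_image)) beta_image <- stats::setNames(numeric(length(il)), il)
  utility_model(beta_topic = beta_topic, beta_image = beta_image,
                noise_scale = noise_scale,
                optout = list(intercept = optout_intercept, quit_intention = 0,
                              quit_attempt = 0, education = 0, income = 0,
                              hsi = 0, re_sd = re_sd),
                ...)
}

# brute-force pair co-occurrence count over a design's sets
brute_pair_counts <- function(design) {
  ids <- design$profiles$profile_id
  cnt <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (S in design$sets) {
    idx <- match(S, ids)
    for (i in seq_along(idx)) for (j in seq_along(idx)) if (i < j) {
      cnt[idx[i], idx[j]] <- cnt[idx[i], idx[j]] + 1L
      cnt[idx[j], idx[i]] <- cnt[idx[j], idx[i]] + 1L
    }
  }
  cnt
}

# minimal bw_fit stand-in for concordance tests
fake_fit <- function(estimates, ps, attribute = "topic") {
  pw <- data.frame(attribute = attribute, stratum = "overall",
                   level = paste0("l", seq_along(estimates)),
                   estimate = estimates, se = 1, z = estimates,
                   p = ps, stringsAsFactors = FALSE)
  structure(list(partworths = pw), class = "bw_fit")
}
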