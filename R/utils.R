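# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed
#'
#' Every stage of the pipeline draws its randomness from a named substream of
#' one master seed, so stages can be re-run in isolation and still reproduce
#' the full-pipeline output.
#'
#' @param master integer master seed.
#' @param name character substream label, e.g. `"cohort"` or `"choices:dce1"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(master) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Round to whole units, halves away from zero (so 14.5 -> 15, -14.5 -> -15).
# Used for reported whole-percent importance shares.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
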