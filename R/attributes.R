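# Attribute specifications, matching constraints, and profile enumeration.

#' Define a message attribute
#'
#' An attribute is a named set of discrete levels, playing either the
#' message-topic or the imagery role in an experiment. Alternatives
#' ("profiles") are formed as topic x imagery combinations.
#'
#' @param name character attribute label, e.g. `"topic"`.
#' @param levels character vector of at least two unique level labels.
#' @param role `"topic"` or `"imagery"`.
#' @return An object of class `bw_attribute`.
#' @examples
#' attribute_spec("topic", c("lung health", "diabetes", "new disease",
#'                           "wellbeing", "financial"), "topic")
#' @export
attribute_spec <- function(name, levels, role = c("topic", "imagery")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L) stop("an attribute needs at least 2 levels", call. = FALSE)
  if (anyDuplicated(levels)) stop("level labels must be unique within an attribute", call. = FALSE)
  structure(list(name = name, levels = levels, role = role), class = "bw_attribute")
}

#' @export
print.bw_attribute <- function(x, ...) {
  cat(sprintf("<bw_attribute> %s (%s): %s\n", x$name, x$role,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Define which topic-imagery combinations are meaningful
#'
#' Some imagery only fits certain topics (e.g. family imagery for a message
#' that mentions a father). The match matrix restricts profile enumeration to
#' the meaningful cells; the default is unconstrained (all combinations
#' allowed).
#'
#' @param topics,images `bw_attribute` objects.
#' @param allowed logical matrix, topics in rows and imagery in columns;
#'   `NULL` for unconstrained.
#' @return An object of class `bw_match` (logical matrix with dimnames).
#' @export
match_matrix <- function(topics, images, allowed = NULL) {
  stopifnot(inherits(topics, "bw_attribute"), inherits(images, "bw_attribute"))
  nt <- length(topics$levels); ni <- length(images$levels)
  if (is.null(allowed)) allowed <- matrix(TRUE, nt, ni)
  allowed <- as.matrix(allowed)
  if (!is.logical(allowed) || nrow(allowed) != nt || ncol(allowed) != ni)
    stop("`allowed` must be a logical ", nt, " x ", ni, " matrix", call. = FALSE)
  if (any(rowSums(allowed) == 0L))
    stop("every topic must match at least one image", call. = FALSE)
  dimnames(allowed) <- list(topics$levels, images$levels)
  class(allowed) <- c("bw_match", class(allowed))
  allowed
}

#' Enumerate the allowed topic-imagery profiles
#'
#' Returns every allowed (topic, imagery) combination as one profile row, in
#' deterministic topic-major order, with dense integer ids `0..v-1`.
#'
#' @param topics,images `bw_attribute` objects.
#' @param match optional `bw_match` constraint; `NULL` means all combinations.
#' @return A data frame with columns `profile_id`, `topic`, `imagery`.
#' @examples
#' t5 <- attribute_spec("topic", paste("topic", 1:5), "topic")
#' i5 <- attribute_spec("imagery", paste("image", 1:5), "imagery")
#' nrow(enumerate_profiles(t5, i5))  # 25
#' @export
enumerate_profiles <- function(topics, images, match = NULL) {
  stopifnot(inherits(topics, "bw_attribute"), inherits(images, "bw_attribute"))
  if (is.null(match)) match <- match_matrix(topics, images)
  if (!all(dim(match) == c(length(topics$levels), length(images$levels))))
    stop("match matrix dimensions do not agree with the attribute level counts",
         call. = FALSE)
  if (any(rowSums(unclass(match)) == 0L))
    stop("every topic must match at least one image", call. = FALSE)
  grid <- expand.grid(imagery = images$levels, topic = topics$levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("topic", "imagery")]
  keep <- mapply(function(t, i) match[t, i], grid$topic, grid$imagery)
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  data.frame(profile_id = seq_len(nrow(out)) - 1L, out, stringsAsFactors = FALSE)
}
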