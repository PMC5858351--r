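# Construction of pairwise-balanced best-worst choice designs.
#
# A choice design here is a 2-(v, k, 1) packing-turned-design: v profiles
# arranged into b = v(v-1)/(k(k-1)) choice sets of k alternatives such that
# every unordered pair of profiles co-occurs in exactly one set ("pairwise
# independent alternatives"). Each profile then appears in exactly
# r = (v-1)/(k-1) sets.

feasibility_check <- function(v, k) {
  if (k < 2L || v < k) stop("need v >= k >= 2", call. = FALSE)
  if ((v - 1L) %% (k - 1L) != 0L || (v * (v - 1L)) %% (k * (k - 1L)) != 0L)
    stop(sprintf(paste0("no 2-(%d,%d,1) design exists: require (k-1) | (v-1) ",
                        "and k(k-1) | v(v-1)"), v, k), call. = FALSE)
  invisible(TRUE)
}

# ---- stage 1: hill-climbing pair cover ------------------------------------
# Grow one set at a time from a random uncovered pair, preferring points
# whose pairs with the partial set are all uncovered; when none exists, allow
# a single existing set to be evicted (its pairs become uncovered again).
# Restart from scratch when no full design emerges within the move budget.
climb_pair_cover <- function(v, k, seed, max_iter = 200000L, restarts = 40L) {
  b <- (v * (v - 1L)) %/% (k * (k - 1L))
  for (rs in seq_len(restarts)) {
    set.seed((seed + (rs - 1L) * 7919L) %% 2147483647)
    cov <- matrix(0L, v, v)                  # slot covering each pair, 0 = none
    blocks <- vector("list", b); occupied <- logical(b); nb <- 0L
    for (iter in seq_len(max_iter)) {
      if (nb == b) return(lapply(blocks[occupied], sort))
      unc <- which(cov == 0L & upper.tri(cov), arr.ind = TRUE)
      p <- unc[sample.int(nrow(unc), 1L), ]
      S <- c(p[[1L]], p[[2L]]); ev <- 0L; ok <- TRUE
      while (length(S) < k) {
        cand <- setdiff(seq_len(v), S)
        confs <- lapply(cand, function(c0) setdiff(unique(cov[c0, S]), c(0L, ev)))
        nconf <- lengths(confs)
        free <- cand[nconf == 0L]
        if (length(free)) {
          c0 <- free[sample.int(length(free), 1L)]
        } else if (ev == 0L && any(nconf == 1L)) {
          one <- which(nconf == 1L)
          i <- one[sample.int(length(one), 1L)]
          c0 <- cand[i]; ev <- confs[[i]][1L]
        } else { ok <- FALSE; break }
        S <- c(S, c0)
      }
      if (!ok) next
      if (ev > 0L) {
        B <- blocks[[ev]]; cp <- t(utils::combn(B, 2L))
        cov[cp] <- 0L; cov[cp[, 2:1, drop = FALSE]] <- 0L
        occupied[ev] <- FALSE; nb <- nb - 1L
      }
      slot <- which(!occupied)[1L]
      blocks[[slot]] <- S; occupied[slot] <- TRUE; nb <- nb + 1L
      cp <- t(utils::combn(sort(S), 2L))
      cov[cp] <- slot; cov[cp[, 2:1, drop = FALSE]] <- slot
    }
  }
  NULL
}

# ---- stage 2: difference-family search ------------------------------------
# When v is prime (group Z_v) or v = p^2 for p prime (group Z_p x Z_p) and
# s = (v-1)/(k(k-1)) is an integer, a 2-(v,k,1) design arises from s base
# blocks whose internal differences partition the nonzero group elements,
# developed by all v group translations. The base blocks are found by a
# seeded randomized depth-first search over candidate blocks.
group_ops <- function(v) {
  p <- as.integer(round(sqrt(v)))
  if (p * p == v && all(p %% seq(2L, max(2L, p - 1L)) != 0L) && p >= 2L) {
    list(add = function(a, b) ((a %% p + b %% p) %% p) + p * ((a %/% p + b %/% p) %% p),
         sub = function(a, b) ((a %% p - b %% p) %% p) + p * ((a %/% p - b %/% p) %% p))
  } else if (v >= 2L && all(v %% seq(2L, max(2L, as.integer(floor(sqrt(v))))) != 0L)) {
    list(add = function(a, b) (a + b) %% v, sub = function(a, b) (a - b) %% v)
  } else NULL
}

difference_family_design <- function(v, k, seed) {
  s <- (v - 1L) / (k * (k - 1L))
  if (s != round(s)) return(NULL)
  g <- group_ops(v)
  if (is.null(g) || choose(v - 1L, k - 1L) > 1e5) return(NULL)
  s <- as.integer(s)
  cands <- utils::combn(seq_len(v - 1L), k - 1L, simplify = FALSE)
  keep <- list()
  for (B in cands) {
    B <- c(0L, B)
    d <- integer(0)
    for (i in seq_len(k)) d <- c(d, g$sub(B[i], B[-i]))
    if (!anyDuplicated(d)) keep[[length(keep) + 1L]] <- list(B = B, d = sort(d))
  }
  if (!length(keep)) return(NULL)
  set.seed(seed %% 2147483647)
  ord <- sample.int(length(keep))
  dmat <- vapply(keep, function(x) x$d, numeric(k * (k - 1L)))
  # DFS for s blocks with pairwise disjoint difference sets
  found <- NULL
  dfs <- function(chosen, used, from) {
    if (length(chosen) == s) { found <<- chosen; return(TRUE) }
    for (ii in from:length(ord)) {
      i <- ord[ii]
      if (any(dmat[, i] %in% used)) next
      if (dfs(c(chosen, i), c(used, dmat[, i]), ii + 1L)) return(TRUE)
    }
    FALSE
  }
  if (!dfs(integer(0), integer(0), 1L)) return(NULL)
  blocks <- list()
  for (i in found)
    for (t in 0:(v - 1L))
      blocks[[length(blocks) + 1L]] <- sort(g$add(keep[[i]]$B, t)) + 1L
  blocks
}

#' Build a pairwise-balanced best-worst choice design
#'
#' Arranges `v` profiles into `v(v-1)/(k(k-1))` choice sets of size `k` such
#' that every unordered pair of profiles appears together in exactly one set,
#' and every profile appears in exactly `(v-1)/(k-1)` sets. The constructor
#' is a seeded randomized search: a hill-climbing pair cover with restarts,
#' followed (for group-structured `v`) by a seeded randomized
#' difference-family search developed over group translations. Output is
#' deterministic for fixed `(profiles, set_size, seed)`.
#'
#' @param profiles profile data frame from [enumerate_profiles()].
#' @param set_size number of alternatives per choice set (default 4).
#' @param seed integer seed for the randomized search.
#' @param max_iter,restarts hill-climbing budget per restart and number of
#'   restarts before falling through to the difference-family stage.
#' @return An object of class `bw_design` with elements `profiles`, `sets`
#'   (list of integer vectors of profile ids), `k`, `seed`, `blocks`.
#' @examples
#' t5 <- attribute_spec("topic", paste("topic", 1:5), "topic")
#' i5 <- attribute_spec("imagery", paste("image", 1:5), "imagery")
#' d <- build_pairwise_balanced_design(enumerate_profiles(t5, i5), seed = 1)
#' length(d$sets)  # 50
#' @export
build_pairwise_balanced_design <- function(profiles, set_size = 4L, seed,
                                           max_iter = 200000L, restarts = 40L) {
  stopifnot(is.data.frame(profiles), all(c("profile_id", "topic", "imagery")
                                         %in% names(profiles)))
  v <- nrow(profiles); k <- as.integer(set_size)
  feasibility_check(v, k)
  blocks <- if (v == k) list(seq_len(v)) else NULL
  if (is.null(blocks))
    blocks <- difference_family_design(v, k, seed)
  if (is.null(blocks))
    blocks <- climb_pair_cover(v, k, seed, max_iter = max_iter, restarts = restarts)
  if (is.null(blocks))
    stop(sprintf(paste0("search budget exhausted for the 2-(%d,%d,1) design; ",
                        "retry with a different seed or a larger budget"), v, k),
         call. = FALSE)
  # seeded relabeling of points and shuffle of set order, so that designs
  # from the algebraic stage also vary with the seed
  set.seed((seed + 104729L) %% 2147483647)
  relab <- sample.int(v)
  blocks <- lapply(blocks, function(B) sort(relab[B]))
  blocks <- blocks[sample.int(length(blocks))]
  sets <- lapply(blocks, function(B) profiles$profile_id[B])
  structure(list(profiles = profiles, sets = sets, k = k, seed = as.integer(seed),
                 blocks = NULL),
            class = "bw_design")
}

#' @export
print.bw_design <- function(x, ...) {
  cat(sprintf("<bw_design> %d profiles, %d choice sets of %d%s (seed %d)\n",
              nrow(x$profiles), length(x$sets), x$k,
              if (is.null(x$blocks)) "" else
                sprintf(", %d blocks", length(x$blocks)), x$seed))
  invisible(x)
}

#' Partition the choice sets into respondent blocks
#'
#' Greedy seeded assignment of choice sets to blocks of the given sizes,
#' keeping the per-profile exposure within each block as even as possible
#' (each set goes to the non-full block where its profiles are currently
#' least exposed).
#'
#' @param design a `bw_design`.
#' @param block_sizes integer vector summing to the number of choice sets,
#'   e.g. `rep(5, 10)` or `c(5, 4, 4)`.
#' @param seed integer seed for the assignment order.
#' @return The design with a `blocks` element: a list of integer vectors of
#'   set indices (1-based into `design$sets`).
#' @export
partition_into_blocks <- function(design, block_sizes, seed) {
  stopifnot(inherits(design, "bw_design"))
  block_sizes <- as.integer(block_sizes)
  nset <- length(design$sets)
  if (sum(block_sizes) != nset)
    stop(sprintf("block sizes sum to %d but the design has %d choice sets",
                 sum(block_sizes), nset), call. = FALSE)
  v <- nrow(design$profiles)
  nb <- length(block_sizes)
  exposure <- matrix(0L, nb, v)           # per-block per-profile counts
  fill <- integer(nb)
  assign_to <- integer(nset)
  set.seed(seed %% 2147483647)
  for (s in sample.int(nset)) {
    idx <- match(design$sets[[s]], design$profiles$profile_id)
    open <- which(fill < block_sizes)
    crowd <- vapply(open, function(bk) sum(exposure[bk, idx]), numeric(1))
    bk <- open[which.min(crowd)]
    assign_to[s] <- bk
    exposure[bk, idx] <- exposure[bk, idx] + 1L
    fill[bk] <- fill[bk] + 1L
  }
  design$blocks <- lapply(seq_len(nb), function(bk) which(assign_to == bk))
  design
}

#' Balance diagnostics for a choice design
#'
#' @param design a `bw_design`.
#' @return A list with `pair_counts` (v x v co-occurrence matrix),
#'   `profile_freq` (per-profile set counts), `block_exposure` (per-block
#'   per-profile counts, when blocks exist), and `pair_coverage_ok` (TRUE iff
#'   every unordered pair co-occurs exactly once and no set repeats a
#'   profile).
#' @export
design_diagnostics <- function(design) {
  stopifnot(inherits(design, "bw_design"))
  ids <- design$profiles$profile_id
  v <- length(ids)
  pc <- matrix(0L, v, v, dimnames = list(ids, ids))
  dup <- FALSE
  for (S in design$sets) {
    if (anyDuplicated(S)) { dup <- TRUE; next }
    idx <- match(S, ids)
    cp <- t(utils::combn(idx, 2L))
    pc[cp] <- pc[cp] + 1L
    pc[cp[, 2:1, drop = FALSE]] <- pc[cp[, 2:1, drop = FALSE]] + 1L
  }
  freq <- vapply(seq_len(v), function(i)
    sum(vapply(design$sets, function(S) ids[i] %in% S, logical(1))), integer(1))
  names(freq) <- ids
  be <- NULL
  if (!is.null(design$blocks)) {
    be <- t(vapply(design$blocks, function(bk) {
      cnt <- integer(v)
      for (s in bk) { idx <- match(design$sets[[s]], ids); cnt[idx] <- cnt[idx] + 1L }
      cnt
    }, integer(v)))
    colnames(be) <- ids
  }
  off <- pc[upper.tri(pc)]
  list(pair_counts = pc, profile_freq = freq, block_exposure = be,
       pair_coverage_ok = !dup && all(off == 1L))
}

#' Serialize a design to JSON
#'
#' @param design a `bw_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  diag <- design_diagnostics(design)
  obj <- list(
    k = design$k, seed = design$seed,
    profiles = design$profiles,
    sets = lapply(design$sets, identity),
    blocks = design$blocks %||% list(),
    diagnostics = list(pair_coverage_ok = diag$pair_coverage_ok,
                       profile_freq = as.integer(diag$profile_freq))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a design back from JSON
#'
#' @param path file written by [write_design()].
#' @return A `bw_design`.
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  relist <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) as.integer(x[i, ]))
    else lapply(x, as.integer)
  }
  blocks <- if (length(obj$blocks)) relist(obj$blocks) else NULL
  structure(list(profiles = as.data.frame(obj$profiles),
                 sets = relist(obj$sets),
                 k = as.integer(obj$k), seed = as.integer(obj$seed),
                 blocks = blocks),
            class = "bw_design")
}

#' Flatten a design to a long table
#'
#' @param design a `bw_design`.
#' @return A data frame with one row per alternative: `set_id` (1-based),
#'   `position`, `profile_id`, `topic`, `imagery`, and `block` when blocks
#'   have been assigned.
#' @export
design_table <- function(design) {
  rows <- do.call(rbind, lapply(seq_along(design$sets), function(s) {
    ids <- design$sets[[s]]
    data.frame(set_id = s, position = seq_along(ids), profile_id = ids)
  }))
  rows <- merge(rows, design$profiles, by = "profile_id", sort = FALSE)
  rows <- rows[order(rows$set_id, rows$position), c("set_id", "position",
                                                    "profile_id", "topic", "imagery")]
  if (!is.null(design$blocks)) {
    bmap <- integer(length(design$sets))
    for (bk in seq_along(design$blocks)) bmap[design$blocks[[bk]]] <- bk
    rows$block <- bmap[rows$set_id]
  }
  rownames(rows) <- NULL
  rows
}
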