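# Fragment weighting, global/local colinear chaining of per-pattern matches,
# overlap filtering.

#' Maximal weight and fragment weight of a pattern
#'
#' The maximal weight a pattern can gain in an alignment is
#' `m * mismatch + bps * arc_removing` (every base mismatching, every arc
#' removed would cost exactly this much, so a perfect match saves it all).
#' A match of cost `c` weighs `max_pattern_weight(q) - c`; matches satisfy
#' `c <= K`, so configuring `K < max_pattern_weight(q)` guarantees positive
#' weights, as colinear chaining requires. A non-positive weight triggers a
#' warning.
#'
#' @param q An [rssp()].
#' @param costs A [cost_model()].
#' @param cost Match cost (sequence-structure edit distance).
#' @return A single numeric weight.
#' @export
#' @examples
#' fragment_weight(rssp("AAGUUUC", "..(...)"), 5)  # 7*1 + 1*2 - 5 = 4
max_pattern_weight <- function(q, costs = cost_model()) {
  length(q) * costs$mismatch + nrow(q$pairs) * costs$arc_removing
}

#' @rdname max_pattern_weight
#' @export
fragment_weight <- function(q, cost, costs = cost_model()) {
  stopifnot(cost >= 0)
  w <- max_pattern_weight(q, costs) - cost
  if (any(w <= 0)) {
    warning("non-positive fragment weight; raise operation costs or lower the ",
            "cost threshold below the pattern's maximal weight")
  }
  w
}

#' Remove overlapping lower-weight matches of the same pattern
#'
#' For each pattern (per sequence and strand), removes every match whose
#' interval overlaps a higher-weight match of the same pattern. Ties are
#' broken in favour of the lower start, then the shorter length, so exactly
#' one of several identical matches survives.
#'
#' @param matches Match data.frame as returned by the search engines (possibly
#'   several patterns, sequences and strands combined).
#' @return The filtered match data.frame.
#' @export
overlap_filter <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  groups <- split(seq_len(nrow(matches)),
                  paste(matches$seqid, matches$strand, matches$pattern, sep = "\r"))
  keep <- integer(0L)
  for (idx in groups) {
    ord <- idx[order(-matches$weight[idx], matches$start[idx],
                     matches$length[idx])]
    taken <- integer(0L)
    for (i in ord) {
      if (!any(matches$start[i] <= matches$end[taken] &
                 matches$end[i] >= matches$start[taken])) {
        taken <- c(taken, i)
      }
    }
    keep <- c(keep, taken)
  }
  out <- matches[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# fragments: match rows + pattern_index; chains combine one or more fragments
# with strictly increasing pattern index and non-overlapping, increasing
# target intervals; chain score = sum of fragment weights.
.prepare_fragments <- function(matches, ssd) {
  nms <- vapply(ssd$patterns, function(q) q$name, "")
  pidx <- match(matches$pattern, nms)
  if (anyNA(pidx)) {
    stop("matches contain patterns not in the SSD: ",
         paste(unique(matches$pattern[is.na(pidx)]), collapse = ", "))
  }
  matches$pattern_index <- pidx
  matches[order(matches$start, matches$end, matches$pattern_index), ,
          drop = FALSE]
}

.chain_frame <- function(frags, chains, scores) {
  if (length(chains) == 0L) {
    return(data.frame(chain = integer(0L), score = numeric(0L),
                      seqid = character(0L), strand = character(0L),
                      pattern = character(0L), pattern_index = integer(0L),
                      start = integer(0L), end = integer(0L),
                      cost = numeric(0L), weight = numeric(0L),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-scores)
  out <- NULL
  for (ci in seq_along(ord)) {
    rows <- frags[chains[[ord[ci]]], , drop = FALSE]
    out <- rbind(out, data.frame(
      chain = ci, score = scores[ord[ci]],
      seqid = rows$seqid, strand = rows$strand, pattern = rows$pattern,
      pattern_index = rows$pattern_index, start = rows$start, end = rows$end,
      cost = rows$cost, weight = rows$weight, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# chaining DP within one (seqid, strand) group; returns list(chains, scores);
# sparse O(k^2) DP over fragments sorted by start, backtracking all optimal
# predecessor choices (capped)
.chain_group <- function(fr, ssd, global, min_score, max_chains) {
  np <- length(ssd$patterns)
  k <- nrow(fr)
  if (k == 0L) return(list(chains = list(), scores = numeric(0L)))
  score <- fr$weight
  best <- numeric(k)         # best chain score ending at fragment i
  prev <- vector("list", k)  # optimal predecessors (0 = chain start)
  for (i in seq_len(k)) {
    p <- fr$pattern_index[i]
    cand <- which(fr$end < fr$start[i] &
                    (if (global) fr$pattern_index == p - 1L
                     else fr$pattern_index < p))
    cand <- cand[is.finite(best[cand])]
    if (global && p > 1L) {
      if (length(cand) == 0L) { best[i] <- -Inf; prev[[i]] <- integer(0L); next }
      bs <- max(best[cand])
      best[i] <- bs + score[i]
      prev[[i]] <- cand[best[cand] == bs]
    } else if (length(cand) == 0L || max(best[cand]) <= 0) {
      best[i] <- score[i]
      prev[[i]] <- 0L
    } else {
      bs <- max(best[cand])
      best[i] <- bs + score[i]
      prev[[i]] <- cand[best[cand] == bs]
    }
  }
  if (global) {
    ends <- which(fr$pattern_index == np & is.finite(best))
  } else {
    # local: maximal chains only -- the last fragment has no colinear
    # successor (positive weights make every extension score higher)
    has_succ <- vapply(seq_len(k), function(i) {
      any(fr$start > fr$end[i] & fr$pattern_index > fr$pattern_index[i])
    }, TRUE)
    ends <- which(!has_succ & is.finite(best))
  }
  ends <- ends[best[ends] >= min_score]
  ends <- ends[order(-best[ends])]
  chains <- list(); scores <- numeric(0L)
  for (e in ends) {
    stack <- list(e)
    while (length(stack) > 0L && length(chains) < max_chains) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (p in prev[[path[1L]]]) {
        if (p == 0L) {
          chains[[length(chains) + 1L]] <- path
          scores <- c(scores, best[e])
        } else {
          stack[[length(stack) + 1L]] <- c(p, path)
        }
        if (length(chains) >= max_chains) break
      }
    }
    if (length(chains) >= max_chains) break
  }
  list(chains = chains, scores = scores)
}

#' Global chains of SSD pattern matches
#'
#' Combines per-pattern matches into chains containing exactly one fragment
#' per SSD pattern, in SSD order, colinear and non-overlapping on the same
#' sequence and strand. The chain score is the plain sum of the fragment
#' weights; chains are reported in descending score order, all co-optimal
#' chains first, down to `min_score`.
#'
#' @param matches Match data.frame (with `weight`), e.g. from
#'   [search_patterns()] or the engines.
#' @param ssd The [ssd()] searched.
#' @param min_score Report threshold.
#' @param max_chains Cap on the number of reported chains per sequence/strand.
#' @return data.frame with one row per chain member: `chain` (rank), `score`,
#'   fragment columns.
#' @export
global_chains <- function(matches, ssd, min_score = 0, max_chains = 100L) {
  .chains(matches, ssd, TRUE, min_score, max_chains)
}

#' Local chains of SSD pattern matches
#'
#' As [global_chains()], but a chain may use any non-empty subsequence of the
#' SSD patterns (order preserved). Only maximal chains are reported: a chain
#' extendable to a higher-scoring chain containing it is suppressed (weights
#' are positive, so any extension scores higher).
#'
#' @inheritParams global_chains
#' @export
local_chains <- function(matches, ssd, min_score = 0, max_chains = 100L) {
  .chains(matches, ssd, FALSE, min_score, max_chains)
}

.chains <- function(matches, ssd, global, min_score, max_chains) {
  frags <- .prepare_fragments(matches, ssd)
  if (nrow(frags) == 0L) return(.chain_frame(frags, list(), numeric(0L)))
  groups <- split(seq_len(nrow(frags)),
                  paste(frags$seqid, frags$strand, sep = "\r"))
  all_chains <- list(); all_scores <- numeric(0L); all_rows <- list()
  for (idx in groups) {
    fr <- frags[idx, , drop = FALSE]
    res <- .chain_group(fr, ssd, global, min_score, max_chains)
    for (ci in seq_along(res$chains)) {
      all_chains[[length(all_chains) + 1L]] <- idx[res$chains[[ci]]]
      all_scores <- c(all_scores, res$scores[ci])
    }
  }
  .chain_frame(frags, all_chains, all_scores)
}
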