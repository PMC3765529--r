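# The four search engines behind one match semantics.

.match_frame <- function(seqid, starts, lens, costs, inds, pattern, strand,
                         weight_max) {
  out <- data.frame(
    seqid = rep(seqid, length(starts)),
    start = as.integer(starts),
    end = as.integer(starts + lens - 1L),
    length = as.integer(lens),
    strand = rep(strand, length(starts)),
    pattern = rep(pattern, length(starts)),
    cost = as.numeric(costs),
    indels = as.numeric(inds),
    weight = as.numeric(weight_max - costs),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.engine_result <- function(res, q, seqid, strand, costs) {
  wmax <- max_pattern_weight(q, costs)
  out <- .match_frame(seqid, res$start, res$len, res$cost, res$indels,
                      q$name, strand, wmax)
  attr(out, "cells") <- res$cells
  attr(out, "stops") <- res$stops
  if (!is.null(res$events)) attr(out, "events") <- res$events
  out
}

.check_searchable <- function(q, n, d) {
  if (n < max(1L, length(q) - d)) {
    warning("target shorter than the minimum match length m - d; no matches possible")
    return(FALSE)
  }
  TRUE
}

#' Online search: sliding window with last-column reuse
#'
#' `scan_align` slides a window of length `m + d` over the target, computing
#' the full DP for the first window and only the last column of every matrix
#' per one-position shift. For every window start and every candidate length
#' `p'` in `[m-d, m+d]` it reports a match when the distance is at most `K`
#' and an optimal alignment with at most `d` indels exists.
#'
#' `lscan_align` reports the identical match set but aligns the pattern
#' region by region, applies the early-stop band test after every computed
#' row, skips the rest of a window on failure, and reuses region columns
#' across overlapping windows (the Z-array bookkeeping).
#'
#' @param q An [rssp()].
#' @param s Target sequence (string; a name is used as the sequence id).
#' @param K Cost threshold (defaults to the pattern's `cost`).
#' @param d Indel budget (defaults to the pattern's `indels`).
#' @param costs A [cost_model()].
#' @param rules A [base_pair_rules()] object.
#' @param seqid Sequence identifier for the report.
#' @param strand Strand label for the report.
#' @return data.frame of matches (`seqid`, `start`, `end`, `length`, `strand`,
#'   `pattern`, `cost`, `indels`, `weight`), ordered by start then length,
#'   with attributes `cells` (computed DP cells) and `stops` (early-stopped
#'   windows; always 0 for `scan_align`).
#' @export
#' @examples
#' q <- rssp("AAGUUUC", "..(...)", cost = 5, indels = 1)
#' scan_align(q, "CCACCCCCCACCCACCACCCUCUU")
scan_align <- function(q, s, K = q$cost, d = q$indels, costs = cost_model(),
                       rules = base_pair_rules(),
                       seqid = if (!is.null(names(s))) names(s)[1L] else "seq",
                       strand = "+") {
  s <- normalize_sequence(as.character(s)[1L])
  if (!.check_searchable(q, nchar(s), d)) {
    return(.engine_result(list(start = integer(0), len = integer(0),
                               cost = numeric(0), indels = numeric(0),
                               cells = 0, stops = 0), q, seqid, strand, costs))
  }
  res <- cpp_scan(q$masks, .q_partner(q), .costs_vec(costs), .comp_matrix(rules),
                  .encode_seq(s), as.numeric(K), as.integer(d), FALSE,
                  .region_matrix(q))
  .engine_result(res, q, seqid, strand, costs)
}

#' @rdname scan_align
#' @export
lscan_align <- function(q, s, K = q$cost, d = q$indels, costs = cost_model(),
                        rules = base_pair_rules(),
                        seqid = if (!is.null(names(s))) names(s)[1L] else "seq",
                        strand = "+") {
  s <- normalize_sequence(as.character(s)[1L])
  if (!.check_searchable(q, nchar(s), d)) {
    return(.engine_result(list(start = integer(0), len = integer(0),
                               cost = numeric(0), indels = numeric(0),
                               cells = 0, stops = 0), q, seqid, strand, costs))
  }
  res <- cpp_scan(q$masks, .q_partner(q), .costs_vec(costs), .comp_matrix(rules),
                  .encode_seq(s), as.numeric(K), as.integer(d), TRUE,
                  .region_matrix(q))
  .engine_result(res, q, seqid, strand, costs)
}

#' Index-based search over the enhanced suffix array
#'
#' `lesa_align` traverses the suffix array top-down, computing the
#' sequence-structure distance of the pattern and each suffix up to its
#' reading depth `min(m + d, |suffix|)`. It reuses DP columns covered by the
#' lcp with the previously computed suffix for already-computed regions, skips
#' whole rank ranges whose shared prefix decides the outcome (emitting matches
#' for all ranks when the predecessor matched), and early-stops per region,
#' then skipping every rank that shares the failing prefix.
#'
#' `lgslink_align` reports the identical match set and additionally (a) after
#' an early stop on an interior region, marks via generalized suffix links
#' every rank whose suffix contains the failing substring at the failing
#' offset, and (b) after each processed rank follows the suffix-link chain,
#' recomputing only last columns by the window-shift update, marking processed
#' ranks so none is handled twice.
#'
#' @param q An [rssp()].
#' @param esa A [build_esa()] index of the target.
#' @param K,d,costs,rules,seqid,strand As in [scan_align()].
#' @param diagnostics If `TRUE`, attach the traversal event log (processed
#'   ranks, marks, stops) as attribute `events`.
#' @return As [scan_align()].
#' @export
lesa_align <- function(q, esa, K = q$cost, d = q$indels, costs = cost_model(),
                       rules = base_pair_rules(), seqid = esa$id, strand = "+",
                       diagnostics = FALSE) {
  .idx_align(q, esa, K, d, costs, rules, seqid, strand, FALSE, diagnostics)
}

#' @rdname lesa_align
#' @export
lgslink_align <- function(q, esa, K = q$cost, d = q$indels, costs = cost_model(),
                          rules = base_pair_rules(), seqid = esa$id,
                          strand = "+", diagnostics = FALSE) {
  .idx_align(q, esa, K, d, costs, rules, seqid, strand, TRUE, diagnostics)
}

.idx_align <- function(q, esa, K, d, costs, rules, seqid, strand, uselinks,
                       diagnostics) {
  stopifnot(inherits(esa, "esa"))
  if (!.check_searchable(q, esa$n, d)) {
    return(.engine_result(list(start = integer(0), len = integer(0),
                               cost = numeric(0), indels = numeric(0),
                               cells = 0, stops = 0), q, seqid, strand, costs))
  }
  regs <- .region_matrix(q, if (uselinks) "index" else "topdown", d)
  res <- cpp_esa_search(q$masks, .q_partner(q), .costs_vec(costs),
                        .comp_matrix(rules), .encode_seq(esa$seq),
                        esa$suf, esa$lcp, esa$isuf,
                        as.numeric(K), as.integer(d), uselinks, regs,
                        diagnostics)
  out <- .engine_result(res, q, seqid, strand, costs)
  if (!diagnostics) attr(out, "events") <- NULL
  out
}

#' Search with any engine
#'
#' Front-end dispatching to the four engines. The engine never changes the
#' match set, only the work done.
#'
#' @param q An [rssp()].
#' @param target Target sequence (string) or a prebuilt [build_esa()] index
#'   (required for the index-based engines unless a string is given, in which
#'   case the index is built on the fly).
#' @param algorithm One of `"scan"`, `"lscan"`, `"lesa"`, `"lgslink"`.
#' @param K,d,costs,rules As in [scan_align()].
#' @param best_per_start If `TRUE`, keep per start position only the
#'   minimum-cost (tie: shortest) match.
#' @param ... Passed to the engine.
#' @return data.frame of matches as in [scan_align()].
#' @export
rssp_search <- function(q, target, algorithm = c("scan", "lscan", "lesa", "lgslink"),
                        K = q$cost, d = q$indels, costs = cost_model(),
                        rules = base_pair_rules(), best_per_start = FALSE, ...) {
  algorithm <- match.arg(algorithm)
  out <- if (algorithm %in% c("scan", "lscan")) {
    s <- if (inherits(target, "esa")) {
      stats::setNames(target$seq, target$id)
    } else target
    if (algorithm == "scan") scan_align(q, s, K, d, costs, rules, ...)
    else lscan_align(q, s, K, d, costs, rules, ...)
  } else {
    esa <- if (inherits(target, "esa")) target else build_esa(target)
    if (algorithm == "lesa") lesa_align(q, esa, K, d, costs, rules, ...)
    else lgslink_align(q, esa, K, d, costs, rules, ...)
  }
  if (best_per_start && nrow(out) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$start), function(idx) {
      idx[order(out$cost[idx], out$length[idx])][1L]
    }), use.names = FALSE)
    atts <- attributes(out)[c("cells", "stops", "events")]
    out <- out[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    for (a in names(atts)) if (!is.null(atts[[a]])) attr(out, a) <- atts[[a]]
  }
  out
}
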