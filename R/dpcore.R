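# The sequence-structure edit model: DP wrappers, helper functions,
# brute-force oracle, cell accounting.

.costs_vec <- function(costs) {
  as.numeric(c(costs$mismatch, costs$indel, costs$arc_breaking,
               costs$arc_altering, costs$arc_removing))
}

.q_partner <- function(q) {
  partner <- integer(length(q))
  if (nrow(q$pairs) > 0L) {
    partner[q$pairs[, 1L]] <- q$pairs[, 2L]
    partner[q$pairs[, 2L]] <- q$pairs[, 1L]
  }
  partner
}

#' Base match indicator
#'
#' `chi(q, t, i, j)` is 0 if target character `t[j]` lies in the IUPAC class of
#' pattern position `i`, otherwise 1 (one unit of mismatch cost).
#'
#' @param q An [rssp()].
#' @param t Target/window text (string).
#' @param i Pattern position.
#' @param j Target position.
#' @return 0 or 1.
#' @export
chi <- function(q, t, i, j) {
  stopifnot(i >= 1, i <= length(q))
  tch <- substr(normalize_sequence(t), j, j)
  code <- match(tch, .BASES)
  if (is.na(code)) return(1L)
  if (bitwAnd(q$masks[i], 2L^(code - 1L)) > 0L) 0L else 1L
}

#' Base complementarity indicator
#'
#' `comp_bases(t, l1, l2, rules)` is 0 if the ordered pair
#' `(t[l1], t[l2])` is in the base-pairing rules, otherwise 1.
#'
#' @param t Target/window text (string).
#' @param l1,l2 Target positions.
#' @param rules [base_pair_rules()].
#' @return 0 or 1.
#' @export
comp_bases <- function(t, l1, l2, rules = base_pair_rules()) {
  stopifnot(l1 != l2)
  t <- normalize_sequence(t)
  a <- substr(t, l1, l1); b <- substr(t, l2, l2)
  if (any(rules[, 1L] == a & rules[, 2L] == b)) 0L else 1L
}

#' Row index function of the DP matrix family
#'
#' Maps a pattern position to the matrix row where the cost of the prefix
#' through that position is stored: the left arc index for a closing position
#' whose combined (prefix + arc) value replaces it, 0 for a left arc index
#' followed by an unpaired position, and the position itself otherwise.
#'
#' @param q An [rssp()].
#' @param i Pattern position in `0..m`.
#' @return Row index.
#' @export
row_fn <- function(q, i) {
  m <- length(q)
  stopifnot(i >= 0, i <= m)
  if (i == 0L) return(0L)
  partner <- .q_partner(q)
  ip <- partner[i]
  sch <- strsplit(q$struct, "")[[1L]]
  if (ip > 0L && ip < i) {  # i closes the arc (ip, i)
    if (ip > 1L && i < m && sch[i + 1L] == "." && sch[ip - 1L] != "(") {
      return(as.integer(ip))
    }
  }
  if (ip > i && i < m && sch[i + 1L] == ".") return(0L)
  as.integer(i)
}

# ---- DP state ------------------------------------------------------------

.dp_state <- function(q, text, costs, rules, reserve = 0L) {
  text <- normalize_sequence(text)
  ptr <- cpp_dp_new(q$masks, .q_partner(q), .costs_vec(costs),
                    .comp_matrix(rules), .encode_seq(text), as.integer(reserve))
  structure(
    list(ptr = ptr, q = q, text = text, costs = costs, rules = rules,
         layout = cpp_dp_layout(q$masks, .q_partner(q))),
    class = "ss_dp"
  )
}

#' Semi-global sequence-structure alignment of a pattern and a window
#'
#' Computes the family of dynamic-programming matrices for aligning the
#' complete pattern `q` against every suffix of the window text `t`, so that
#' the final row of the first matrix holds `dist(q, t[1..j])` for every prefix
#' length `j`. The state retains all matrices for inspection, traceback and
#' incremental updates ([dp_shift()], [dp_reuse_prefix()]).
#'
#' @param q An [rssp()].
#' @param t Window text, typically of length `m + d` (shorter allowed).
#' @param costs A [cost_model()].
#' @param rules A [base_pair_rules()] object.
#' @param reserve Reserve column capacity for later texts longer than `t`.
#' @return An object of class `ss_dp`.
#' @export
#' @examples
#' st <- semiglobal_dp(rssp("AAGUUUC", "..(...)"), "CACCCUC")
#' ss_dist(st)
semiglobal_dp <- function(q, t, costs = cost_model(), rules = base_pair_rules(),
                          reserve = 0L) {
  .dp_state(q, t, costs, rules, reserve)
}

#' Distances from a DP state
#'
#' `dp_final_row(state)` returns the final-row matrix (`cost` and `indels` for
#' every window prefix length `0..|t|`); `ss_dist(state)` returns the distance
#' of the pattern and the full window.
#'
#' @param state An `ss_dp` state.
#' @return `dp_final_row`: numeric matrix; `ss_dist`: single number.
#' @export
dp_final_row <- function(state) {
  stopifnot(inherits(state, "ss_dp"))
  cpp_dp_final(state$ptr)
}

#' @rdname dp_final_row
#' @export
ss_dist <- function(state) {
  fr <- dp_final_row(state)
  unname(fr["cost", ncol(fr)])
}

#' One-call sequence-structure edit distance
#'
#' Convenience wrapper: `dist(q, t)` via the full DP, without retaining state.
#'
#' @inheritParams semiglobal_dp
#' @param with_indels If `TRUE`, return `c(cost, indels)` where `indels` is the
#'   minimum indel count among minimum-cost alignments.
#' @return Distance (or cost/indel pair).
#' @export
ss_edit_dist <- function(q, t, costs = cost_model(), rules = base_pair_rules(),
                         with_indels = FALSE) {
  fr <- cpp_dist(q$masks, .q_partner(q), .costs_vec(costs),
                 .comp_matrix(rules), .encode_seq(normalize_sequence(t)))
  if (with_indels) fr[, ncol(fr)] else unname(fr["cost", ncol(fr)])
}

#' Shift the DP window one position right
#'
#' Implements the last-column update: after appending `new_char` and dropping
#' the first window character, only the last column of every matrix needs
#' computing. Counters in [count_cells()] reflect the shift.
#'
#' @param state An `ss_dp` state.
#' @param new_char Single character entering the window on the right.
#' @return The updated state, invisibly.
#' @export
dp_shift <- function(state, new_char) {
  code <- .encode_seq(normalize_sequence(new_char))[1L]
  cpp_dp_shift(state$ptr, code)
  state$text <- paste0(substr(state$text, 2L, nchar(state$text)), new_char)
  invisible(state)
}

#' Recompute the DP for a new text sharing a prefix
#'
#' Replaces the window text by `t`, reusing columns `j <= shared - k + 1` of
#' every matrix `k` (the columns covered by the shared prefix, as when walking
#' an lcp-sorted suffix array).
#'
#' @param state An `ss_dp` state.
#' @param t New text.
#' @param shared Length of the prefix shared with the previous text.
#' @return The updated state, invisibly.
#' @export
dp_reuse_prefix <- function(state, t, shared) {
  t <- normalize_sequence(t)
  cpp_dp_reuse(state$ptr, .encode_seq(t), as.integer(shared))
  state$text <- t
  invisible(state)
}

#' Cell accounting of a DP state
#'
#' Counts matrix cells over all pattern rows (`m` rows per matrix by
#' convention, columns `1..m'-k+1` of matrix `k`), split into cells computed
#' and cells reused by the most recent operation on the state. A full
#' computation for m = 7, d = 1 yields 252 cells; a one-position window shift
#' recomputes 56; recomputation after a shared prefix of 4 recomputes 182.
#'
#' @param state An `ss_dp` state.
#' @return Named vector `computed`, `reused`, `total`.
#' @export
count_cells <- function(state) {
  stopifnot(inherits(state, "ss_dp"))
  cts <- cpp_dp_counts(state$ptr)
  m <- length(state$q)
  c(computed = unname(cts["computed_slots"]) * m,
    reused = unname(cts["reused_slots"]) * m,
    total = unname(cts["total_slots"]) * m)
}

#' Matrices of a DP state
#'
#' Returns the matrix family: for each start `k`, the `cost` and `indels`
#' matrices over storage rows (see the `layout` element of the state for the
#' mapping of pattern positions to rows).
#'
#' @param state An `ss_dp` state.
#' @return List of per-`k` lists with `cost` and `indels` matrices.
#' @export
dp_matrices <- function(state) {
  stopifnot(inherits(state, "ss_dp"))
  cpp_dp_matrices(state$ptr)
}

# ---- brute-force oracle ----------------------------------------------------

#' Brute-force sequence-structure edit distance (enumeration oracle)
#'
#' Enumerates every alignment (all monotone match-edge sets plus the induced
#' gap edges) and scores each directly from the edit-operation definitions:
#' base mismatch per mismatching match edge and base indel per gap edge (at
#' any position), plus the arc penalties as add-ons -- arc breaking when both
#' partners are matched but not complementary, arc altering when one partner
#' is deleted, arc removing when both are. Exponential; sizes are guarded.
#'
#' @inheritParams semiglobal_dp
#' @param t Target text (full text is aligned, as in one window).
#' @param with_indels If `TRUE`, return `c(cost, indels)` with the minimum
#'   indel count among minimum-cost alignments.
#' @return Minimum alignment cost (or cost/indel pair).
#' @export
brute_force_dist <- function(q, t, costs = cost_model(),
                             rules = base_pair_rules(), with_indels = FALSE) {
  m <- length(q)
  t <- normalize_sequence(t)
  tn <- nchar(t)
  if (m > 8L || tn > 10L) {
    stop("brute_force_dist enumerates all alignments; m <= 8 and |t| <= 10 required")
  }
  tch <- strsplit(t, "")[[1L]]
  tcode <- .encode_seq(t)
  chiM <- matrix(1L, m, max(tn, 1L))
  for (i in seq_len(m)) for (j in seq_len(tn)) {
    chiM[i, j] <- if (tcode[j] < 4L &&
                      bitwAnd(q$masks[i], 2L^tcode[j]) > 0L) 0L else 1L
  }
  cmpM <- .comp_matrix(rules)
  wm <- costs$mismatch; wd <- costs$indel; wb <- costs$arc_breaking
  wa <- costs$arc_altering; wr <- costs$arc_removing
  pairsP <- q$pairs
  paired <- logical(m)
  if (nrow(pairsP) > 0L) paired[c(pairsP[, 1L], pairsP[, 2L])] <- TRUE

  best <- c(Inf, Inf)
  map <- integer(m)
  score_map <- function() {
    cost <- 0; ind <- 0
    nmatch <- sum(map > 0L)
    ins <- tn - nmatch
    cost <- cost + ins * wd; ind <- ind + ins
    for (i in seq_len(m)) {
      if (paired[i]) next
      if (map[i] == 0L) { cost <- cost + wd; ind <- ind + 1 }
      else cost <- cost + chiM[i, map[i]] * wm
    }
    if (nrow(pairsP) > 0L) for (r in seq_len(nrow(pairsP))) {
      k1 <- pairsP[r, 1L]; k2 <- pairsP[r, 2L]
      l1 <- map[k1]; l2 <- map[k2]
      if (l1 > 0L && l2 > 0L) {
        cost <- cost + (chiM[k1, l1] + chiM[k2, l2]) * wm +
          if (cmpM[tcode[l1] + 1L, tcode[l2] + 1L] == 1L) wb else 0
      } else if (l1 == 0L && l2 == 0L) {
        cost <- cost + wr + 2 * wd; ind <- ind + 2
      } else {
        kk <- if (l1 > 0L) k1 else k2
        ll <- max(l1, l2)
        cost <- cost + wa + wd + chiM[kk, ll] * wm; ind <- ind + 1
      }
    }
    if (cost < best[1L] || (cost == best[1L] && ind < best[2L])) {
      best <<- c(cost, ind)
    }
  }
  rec <- function(i, last) {
    if (i > m) { score_map(); return(invisible()) }
    map[i] <<- 0L
    rec(i + 1L, last)
    if (last < tn) for (l in (last + 1L):tn) {
      map[i] <<- l
      rec(i + 1L, l)
      map[i] <<- 0L
    }
  }
  rec(1L, 0L)
  if (with_indels) c(cost = best[1L], indels = best[2L]) else best[1L]
}
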