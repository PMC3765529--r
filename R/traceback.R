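# Recover one optimal alignment from a computed DP state and render it.

.cellv <- function(mats, wd, k, slot, j) {
  if (slot < 0L) return(c(j * wd, j))
  M <- mats[[k]]
  c(M$cost[slot + 1L, j + 1L], M$indels[slot + 1L, j + 1L])
}

.eqv <- function(a, b) all(abs(a - b) < 1e-9)

#' Traceback of an optimal alignment
#'
#' Recovers one minimum-cost alignment (with the minimum number of indels
#' among minimum-cost alignments) of the pattern and the window prefix
#' `t[1..end_col]` from a computed [semiglobal_dp()] state.
#'
#' @param state An `ss_dp` state.
#' @param end_col Window prefix length (defaults to the full window).
#' @return Object of class `ss_alignment`: fields `matches` (two-column matrix
#'   of pattern/target position pairs), `pattern_gaps`, `insertions`, `cost`,
#'   `indels`, plus the pattern and the aligned target substring.
#' @export
traceback_alignment <- function(state, end_col = nchar(state$text)) {
  stopifnot(inherits(state, "ss_dp"))
  q <- state$q
  m <- length(q)
  lay <- state$layout
  mats <- dp_matrices(state)
  if (end_col + 1L > ncol(mats[[1L]]$cost)) stop("end column not computed")
  costs <- state$costs
  wm <- costs$mismatch; wd <- costs$indel; wb <- costs$arc_breaking
  wa <- costs$arc_altering; wr <- costs$arc_removing
  tcode <- .encode_seq(state$text)
  cmp <- .comp_matrix(state$rules)
  partner <- .q_partner(q)
  chi_ <- function(pos, tpos) {
    if (tcode[tpos] < 4L && bitwAnd(q$masks[pos], 2L^tcode[tpos]) > 0L) 0L else 1L
  }
  refslot <- function(j, s) {
    if (j < s) return(-1L)
    if (lay$kind[j] == 0L) return(lay$slot_main[j])
    a <- partner[j]
    if (a == s) lay$slot_main[j] else lay$slot_merged[j]
  }
  edges <- NULL; pgaps <- integer(0L); tgaps <- integer(0L)
  add_edge <- function(i, t) edges <<- rbind(edges, c(i, t))
  cv <- function(k, slot, j) .cellv(mats, wd, k, slot, j)

  tb_prefix <- function(k, endpos, j, s) {
    if (endpos < s) {
      if (j > 0L) tgaps <<- c(tgaps, k + seq_len(j) - 1L)
      return(invisible())
    }
    if (lay$kind[endpos] == 0L) {
      cell <- cv(k, lay$slot_main[endpos], j)
      prev <- refslot(endpos - 1L, s)
      if (j > 0L) {
        if (.eqv(cv(k, prev, j - 1L) + c(chi_(endpos, k + j - 1L) * wm, 0), cell)) {
          add_edge(endpos, k + j - 1L)
          return(tb_prefix(k, endpos - 1L, j - 1L, s))
        }
        if (.eqv(cv(k, lay$slot_main[endpos], j - 1L) + c(wd, 1), cell)) {
          tgaps <<- c(tgaps, k + j - 1L)
          return(tb_prefix(k, endpos, j - 1L, s))
        }
      }
      if (.eqv(cv(k, prev, j) + c(wd, 1), cell)) {
        pgaps <<- c(pgaps, endpos)
        return(tb_prefix(k, endpos - 1L, j, s))
      }
      stop("traceback failed at unpaired row ", endpos)
    }
    a <- partner[endpos]
    if (a == s) return(tb_arc(k, a, endpos, j))
    cell <- cv(k, lay$slot_merged[endpos], j)
    before <- refslot(a - 1L, s)
    for (jp in 0:j) {
      if (.eqv(cv(k, before, jp) + cv(k + jp, lay$slot_main[endpos], j - jp), cell)) {
        tb_prefix(k, a - 1L, jp, s)
        return(tb_arc(k + jp, a, endpos, j - jp))
      }
    }
    stop("traceback failed at merged row ", endpos)
  }

  tb_arc <- function(k, a, b, j) {
    cell <- cv(k, lay$slot_main[b], j)
    inner <- refslot(b - 1L, a + 1L)
    if (j >= 2L) {  # both partners matched
      cc <- cv(k + 1L, inner, j - 2L) +
        c((chi_(a, k) + chi_(b, k + j - 1L)) * wm +
            (if (cmp[tcode[k] + 1L, tcode[k + j - 1L] + 1L] == 1L) wb else 0), 0)
      if (.eqv(cc, cell)) {
        add_edge(a, k); add_edge(b, k + j - 1L)
        return(tb_prefix(k + 1L, b - 1L, j - 2L, a + 1L))
      }
    }
    if (j >= 1L) {
      if (.eqv(cv(k, inner, j - 1L) + c(chi_(b, k + j - 1L) * wm + wa + wd, 1), cell)) {
        add_edge(b, k + j - 1L); pgaps <<- c(pgaps, a)
        return(tb_prefix(k, b - 1L, j - 1L, a + 1L))
      }
      if (.eqv(cv(k + 1L, inner, j - 1L) + c(chi_(a, k) * wm + wa + wd, 1), cell)) {
        add_edge(a, k); pgaps <<- c(pgaps, b)
        return(tb_prefix(k + 1L, b - 1L, j - 1L, a + 1L))
      }
      if (.eqv(cv(k, lay$slot_main[b], j - 1L) + c(wd, 1), cell)) {
        tgaps <<- c(tgaps, k + j - 1L)
        return(tb_arc(k, a, b, j - 1L))
      }
      if (.eqv(cv(k + 1L, lay$slot_main[b], j - 1L) + c(wd, 1), cell)) {
        tgaps <<- c(tgaps, k)
        return(tb_arc(k + 1L, a, b, j - 1L))
      }
    }
    if (.eqv(cv(k, inner, j) + c(wr + 2 * wd, 2), cell)) {
      pgaps <<- c(pgaps, a, b)
      return(tb_prefix(k, b - 1L, j, a + 1L))
    }
    stop("traceback failed at arc row ", b)
  }

  final <- cv(1L, lay$finalslot, end_col)
  tb_prefix(1L, m, end_col, 1L)
  if (is.null(edges)) edges <- matrix(integer(0L), 0L, 2L)
  colnames(edges) <- c("pattern", "target")
  structure(
    list(pattern = q$pattern, struct = q$struct,
         target = substr(state$text, 1L, end_col),
         matches = edges[order(edges[, 1L]), , drop = FALSE],
         pattern_gaps = sort(pgaps), insertions = sort(tgaps),
         cost = final[1L], indels = final[2L]),
    class = "ss_alignment"
  )
}

#' @export
format.ss_alignment <- function(x, ...) {
  m <- nchar(x$pattern)
  tn <- nchar(x$target)
  map <- integer(m)
  if (nrow(x$matches) > 0L) map[x$matches[, 1L]] <- x$matches[, 2L]
  pch <- strsplit(x$pattern, "")[[1L]]
  sch <- strsplit(x$struct, "")[[1L]]
  tch <- strsplit(x$target, "")[[1L]]
  lp <- ls_ <- lb <- lt <- character(0L)
  i <- 1L; t <- 1L
  while (i <= m || t <= tn) {
    nx <- if (i <= m && map[i] > 0L) map[i] else tn + 1L
    if (i <= m && map[i] == 0L) {
      lp <- c(lp, pch[i]); ls_ <- c(ls_, sch[i]); lb <- c(lb, " "); lt <- c(lt, "-")
      i <- i + 1L
    } else if (t < nx) {
      lp <- c(lp, "-"); ls_ <- c(ls_, "-"); lb <- c(lb, " "); lt <- c(lt, tch[t])
      t <- t + 1L
    } else {
      bar <- if (tch[t] %in% iupac_class(pch[i])) "|" else " "
      lp <- c(lp, pch[i]); ls_ <- c(ls_, sch[i]); lb <- c(lb, bar); lt <- c(lt, tch[t])
      i <- i + 1L; t <- t + 1L
    }
  }
  paste0(paste(lp, collapse = ""), "\n", paste(ls_, collapse = ""), "\n",
         paste(lb, collapse = ""), "\n", paste(lt, collapse = ""),
         "\ncost = ", x$cost, ", indels = ", x$indels)
}

#' @export
print.ss_alignment <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Alignment of one reported match
#'
#' Recomputes the DP for the matched substring and returns the optimal
#' alignment for display.
#'
#' @param q The [rssp()] that produced the match.
#' @param s The target sequence searched.
#' @param match One match row (list or one-row data.frame with `start`,
#'   `end`).
#' @param costs,rules As used in the search.
#' @return An `ss_alignment`.
#' @export
match_alignment <- function(q, s, match, costs = cost_model(),
                            rules = base_pair_rules()) {
  s <- normalize_sequence(as.character(s)[1L])
  window <- substr(s, match$start, match$end)
  st <- semiglobal_dp(q, window, costs, rules)
  traceback_alignment(st)
}
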