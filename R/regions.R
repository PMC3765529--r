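# Decomposition of an RSSP into nested regions, region -> DP-row mapping,
# the early-stop band test, and region resorting for index search.

#' Decompose an RSSP into regions
#'
#' Splits the pattern into the regions that drive the early-stopping
#' computation. Each region `Q[x..y]` satisfies exactly one of four
#' conditions:
#'
#' 1. a maximal unpaired run that is a left dangling end (`x = 1`) or directly
#'    follows an opening bracket;
#' 2. `y` unpaired, with at least one complete arc inside `[x..y]` (the region
#'    extends left over whole arcs and unpaired positions until an opening
#'    bracket or the pattern start);
#' 3. an arc `(x, y)`;
#' 4. `y` closes an arc preceded by other material in its segment (`x` is the
#'    segment start: position 1 or just inside the enclosing arc).
#'
#' Regions nest but never partially overlap; the returned order (by `y`,
#' arcs before their merged extension) is the top-down computation order of
#' the DP rows, so every region's dependencies precede it.
#'
#' @param q An [rssp()].
#' @return data.frame with columns `x`, `y`, `condition`.
#' @export
#' @examples
#' decompose_regions(rssp("AAGUUUC", "..(...)"))
decompose_regions <- function(q) {
  m <- length(q)
  sch <- strsplit(q$struct, "")[[1L]]
  partner <- .q_partner(q)
  segstart <- cpp_dp_layout(q$masks, partner)$segstart
  regs <- NULL
  # unpaired runs -> conditions 1 and 2
  u <- 1L
  while (u <= m) {
    if (sch[u] != ".") { u <- u + 1L; next }
    v <- u
    while (v < m && sch[v + 1L] == ".") v <- v + 1L
    # extend x left over complete arcs and unpaired positions
    x <- u; crossed <- FALSE
    repeat {
      if (x == 1L) break
      if (sch[x - 1L] == "(") break
      if (sch[x - 1L] == ".") { x <- x - 1L } else { x <- partner[x - 1L]; crossed <- TRUE }
    }
    regs <- rbind(regs, c(x, v, if (crossed) 2L else 1L))
    u <- v + 1L
  }
  # arcs -> conditions 3 and 4
  if (nrow(q$pairs) > 0L) {
    for (r in seq_len(nrow(q$pairs))) {
      a <- q$pairs[r, 1L]; b <- q$pairs[r, 2L]
      regs <- rbind(regs, c(a, b, 3L))
      if (segstart[a] < a) regs <- rbind(regs, c(segstart[a], b, 4L))
    }
  }
  regs <- as.data.frame(regs)
  names(regs) <- c("x", "y", "condition")
  regs <- regs[order(regs$y, regs$condition), , drop = FALSE]
  rownames(regs) <- NULL
  regs
}

#' Rows of the DP matrices computed for a region
#'
#' Maps a region to the matrix rows it owns and the recurrence used: all rows
#' `x..y` for condition 1; the trailing unpaired rows after the last paired
#' position for condition 2 (both via the unpaired-base recurrence); row `y`
#' via the paired-base recurrence for condition 3; row [row_fn()]`(y)` via the
#' split-column combination for condition 4.
#'
#' @param region One-row data.frame (or list) with `x`, `y`, `condition`.
#' @param q The [rssp()].
#' @return List with `rows` (integer vector) and `rule` (one of `"unpaired"`,
#'   `"arc"`, `"merged"`).
#' @export
rows_for_region <- function(region, q) {
  x <- region$x; y <- region$y; cond <- region$condition
  sch <- strsplit(q$struct, "")[[1L]]
  if (cond == 1L) {
    list(rows = x:y, rule = "unpaired")
  } else if (cond == 2L) {
    yp <- y
    while (yp >= x && sch[yp] == ".") yp <- yp - 1L
    list(rows = (yp + 1L):y, rule = "unpaired")
  } else if (cond == 3L) {
    list(rows = y, rule = "arc")
  } else {
    list(rows = row_fn(q, y), rule = "merged")
  }
}

#' Region dependencies
#'
#' A region depends on the maximal regions strictly inside its interval (their
#' rows must be computed first).
#'
#' @param regions Output of [decompose_regions()].
#' @return List (per region) of integer vectors of region indices.
#' @export
region_dependencies <- function(regions) {
  n <- nrow(regions)
  x <- regions$x; y <- regions$y
  # strict interval containment (region intervals are pairwise distinct)
  inside_of <- function(a, r) x[a] >= x[r] & y[a] <= y[r] & (x[a] > x[r] | y[a] < y[r])
  deps <- vector("list", n)
  for (r in seq_len(n)) {
    inside <- which(vapply(seq_len(n), inside_of, TRUE, r = r))
    if (length(inside) == 0L) { deps[[r]] <- integer(0L); next }
    maximal <- vapply(inside, function(a) {
      !any(vapply(setdiff(inside, a), function(b) inside_of(a, b), TRUE))
    }, TRUE)
    deps[[r]] <- inside[maximal]
  }
  deps
}

#' Resort regions for index-based search
#'
#' Index traversal profits from starting the alignment at a region that does
#' not depend on any other region and whose left flank clears the indel band
#' (`x - d > 1`): a failure there licenses substring-based skipping. The
#' left-most such region is moved to the front; the remaining top-down order
#' is preserved, so all dependencies still precede their dependents. Without a
#' qualifying region the top-down order is returned unchanged.
#'
#' @param regions Output of [decompose_regions()].
#' @param d Indel budget.
#' @return Reordered `regions` data.frame.
#' @export
sort_regions_for_index <- function(regions, d) {
  deps <- region_dependencies(regions)
  free <- which(vapply(deps, length, 1L) == 0L & regions$x - d > 1L)
  if (length(free) == 0L) return(regions)
  first <- free[order(regions$x[free], regions$y[free])][1L]
  out <- regions[c(first, setdiff(seq_len(nrow(regions)), first)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Early-stop band test for a region
#'
#' Tests whether every alignment of the region `Q[x..y]` compatible with at
#' most `d` indels exceeds the cost threshold: the probed cells are those on
#' the region's diagonal band, i.e. `dist(Q[x..y], T_{x+d'}[1..l+z])` for
#' every shift `d'` in `[-d, min(d, x)]` (with `y + d' <= |T|`) and
#' `z` in `{|d'|-d, d-|d'|}`. Cells outside the computed matrices count as
#' exceeding. A `TRUE` result licenses skipping the window or suffix: the
#' full-pattern distance then exceeds `K` for every candidate match length.
#'
#' @param state An `ss_dp` state with the region's rows computed.
#' @param region One-row data.frame (or list) with `x`, `y`, `condition`.
#' @param K Cost threshold.
#' @param d Indel budget.
#' @return `TRUE` if every probed cell exceeds `K`.
#' @export
early_stop_exceeded <- function(state, region, K, d) {
  stopifnot(inherits(state, "ss_dp"))
  lay <- state$layout
  y <- region$y
  slot <- if (region$condition == 4L) lay$slot_merged[y] else lay$slot_main[y]
  if (is.na(slot) || slot < 0L) stop("region rows are not materialized")
  cpp_dp_band(state$ptr, as.integer(region$x), as.integer(y),
              as.integer(slot), as.numeric(K), as.integer(d))
}

# region matrix (x, y, condition) in engine order for the C++ engines
.region_matrix <- function(q, order = c("topdown", "index"), d = 0L) {
  order <- match.arg(order)
  regs <- decompose_regions(q)
  if (order == "index") regs <- sort_regions_for_index(regs, d)
  as.matrix(regs)
}
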