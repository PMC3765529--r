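# Alphabets, IUPAC classes, base-pair rules, RSSP/SSD objects and parsing.

.BASES <- c("A", "C", "G", "U")

.IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), M = c("A", "C"), K = c("G", "U"),
  W = c("A", "U"), S = c("C", "G"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' IUPAC nucleotide character class
#'
#' Expands a pattern symbol to the set of bases it stands for. The four bases
#' each denote themselves; the eleven ambiguity codes denote the standard IUPAC
#' classes, e.g. `R` (purine) is `{A, G}` and `N` is any base.
#'
#' @param symbol A single character out of `A C G U R Y M K W S B D H V N`
#'   (lowercase and `T` accepted; `T` is treated as `U`).
#' @return Character vector of bases in the class.
#' @export
#' @examples
#' iupac_class("N")
#' iupac_class("R")
iupac_class <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nchar(symbol) == 1L)
  s <- toupper(symbol)
  if (s == "T") s <- "U"
  cls <- .IUPAC[[s]]
  if (is.null(cls)) {
    stop("unknown pattern symbol '", symbol, "' (expected IUPAC nucleotide code)")
  }
  cls
}

# bitmask over A=1,C=2,G=4,U=8 for one pattern symbol
.class_mask <- function(symbol) {
  as.integer(sum(2L^(match(iupac_class(symbol), .BASES) - 1L)))
}

# inverse: mask -> IUPAC symbol
.MASK2SYM <- local({
  out <- character(15L)
  for (s in names(.IUPAC)) out[sum(2L^(match(.IUPAC[[s]], .BASES) - 1L))] <- s
  out
})

#' Base-pairing rules
#'
#' The set of ordered base pairs allowed to form an arc. The default is the six
#' canonical pairings: Watson-Crick `(A,U) (U,A) (C,G) (G,C)` plus the wobble
#' pairs `(G,U) (U,G)`. User-defined rules are any subset of the 16 ordered
#' pairs; order is respected (the first base is the 5' arc partner).
#'
#' @param pairs `NULL` for the default rules, or a two-column character matrix /
#'   data.frame of ordered pairs.
#' @return An object of class `bp_rules`: a two-column character matrix.
#' @export
base_pair_rules <- function(pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- cbind(
      c("A", "U", "C", "G", "G", "U"),
      c("U", "A", "G", "C", "U", "G")
    )
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("base-pair rules must have two columns")
  pairs[] <- toupper(pairs)
  pairs[pairs == "T"] <- "U"
  bad <- !(pairs %in% .BASES)
  if (any(bad)) {
    stop("base-pair rules may only use bases A, C, G, U; offending: ",
         paste(unique(pairs[bad]), collapse = ", "))
  }
  pairs <- unique(pairs)
  dimnames(pairs) <- NULL
  structure(pairs, class = "bp_rules")
}

#' Read base-pairing rules from a text file
#'
#' One pair per line, the two bases separated by whitespace. Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the rules file.
#' @return A [base_pair_rules()] object.
#' @export
read_bp_rules <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no base-pair rules found in ", path)
  parts <- strsplit(lines, "\\s+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed base-pair rule line: '", lines[which(bad)[1L]], "'")
  }
  base_pair_rules(do.call(rbind, parts))
}

# 5x5 0/1 complementarity matrix (index base code + 1; code 4 = non-ACGU)
.comp_matrix <- function(rules) {
  m <- matrix(1L, 5L, 5L)
  i <- match(rules[, 1L], .BASES)
  j <- match(rules[, 2L], .BASES)
  m[cbind(i, j)] <- 0L
  m
}

#' Transform base-pair rules for minus-strand search
#'
#' Complements both partners of every rule (keeping order), so that a pattern
#' transformed with [reverse_complement_pattern()] matches the reverse strand
#' through the plus-strand text. The wobble pairs `(G,U), (U,G)` become
#' `(C,A), (A,C)`.
#'
#' @param rules A [base_pair_rules()] object.
#' @return The transformed `bp_rules` object.
#' @export
complement_rules <- function(rules) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  base_pair_rules(cbind(comp[rules[, 1L]], comp[rules[, 2L]]))
}

#' Base-pair table of a dot-bracket string
#'
#' Matches brackets in a structure string over `. ( )` and returns the arcs as
#' a set of (i, j) position pairs with i < j. Pseudoknots cannot be expressed
#' in this notation; unbalanced strings are rejected with the position of the
#' offending bracket.
#'
#' @param struct Dot-bracket string.
#' @return Integer matrix with columns `i`, `j`, one row per arc, ordered by
#'   closing position.
#' @export
#' @examples
#' pair_table("..(...)")
pair_table <- function(struct) {
  chars <- strsplit(struct, "")[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0L) {
    stop("invalid structure character '", chars[bad[1L]], "' at position ", bad[1L])
  }
  stack <- integer(0L)
  pairs <- NULL
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      stack <- c(stack, p)
    } else if (chars[p] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced structure: unmatched ')' at position ", p)
      }
      pairs <- rbind(pairs, c(stack[length(stack)], p))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced structure: unmatched '(' at position ", stack[length(stack)])
  }
  if (is.null(pairs)) pairs <- matrix(integer(0L), 0L, 2L)
  colnames(pairs) <- c("i", "j")
  pairs
}

#' Render a base-pair set as a dot-bracket string
#'
#' Inverse of [pair_table()] for valid (non-crossing) pair sets.
#'
#' @param pairs Two-column integer matrix of arcs.
#' @param m Pattern length.
#' @return Dot-bracket string of length `m`.
#' @export
structure_string <- function(pairs, m) {
  chars <- rep(".", m)
  if (NROW(pairs) > 0L) {
    chars[pairs[, 1L]] <- "("
    chars[pairs[, 2L]] <- ")"
  }
  paste(chars, collapse = "")
}

#' RNA sequence-structure pattern (RSSP)
#'
#' An RSSP couples a sequence pattern over the IUPAC alphabet with a
#' dot-bracket structure string of the same length m, plus the per-pattern
#' search thresholds: the cost threshold `cost` (maximum sequence-structure
#' edit distance of a match) and the indel budget `indels` (maximum number of
#' insertions plus deletions in a match alignment, which also bounds the match
#' length to `[m - indels, m + indels]`).
#'
#' @param pattern Sequence pattern (string over `A C G U` + ambiguity codes;
#'   `T` is read as `U`).
#' @param struct Dot-bracket structure string of the same length.
#' @param name Pattern identifier.
#' @param cost Non-negative cost threshold K.
#' @param indels Non-negative indel budget d.
#' @return Object of class `rssp` with fields `name`, `pattern`, `struct`,
#'   `pairs` (arc table), `cost`, `indels`.
#' @export
#' @examples
#' rssp("AAGUUUC", "..(...)", name = "hairpin", cost = 5, indels = 1)
rssp <- function(pattern, struct, name = "pattern", cost = 0, indels = 0) {
  stopifnot(is.character(pattern), length(pattern) == 1L,
            is.character(struct), length(struct) == 1L)
  pattern <- toupper(pattern)
  pattern <- gsub("T", "U", pattern, fixed = TRUE)
  if (nchar(pattern) != nchar(struct)) {
    stop("pattern '", name, "': sequence length ", nchar(pattern),
         " != structure length ", nchar(struct))
  }
  if (nchar(pattern) == 0L) stop("pattern '", name, "' is empty")
  if (cost < 0 || indels < 0) stop("cost and indels must be non-negative")
  syms <- strsplit(pattern, "")[[1L]]
  masks <- vapply(syms, .class_mask, 1L)  # errors on bad symbol
  pairs <- pair_table(struct)
  q <- structure(
    list(name = as.character(name), pattern = pattern, struct = struct,
         pairs = pairs, cost = as.numeric(cost), indels = as.integer(indels),
         masks = unname(masks)),
    class = "rssp"
  )
  q
}

#' @export
print.rssp <- function(x, ...) {
  cat("RSSP '", x$name, "' (m = ", nchar(x$pattern), ", ",
      nrow(x$pairs), " base pair(s), cost = ", x$cost,
      ", indels = ", x$indels, ")\n", sep = "")
  cat("  ", x$pattern, "\n  ", x$struct, "\n", sep = "")
  invisible(x)
}

#' @export
length.rssp <- function(x) nchar(x$pattern)

#' Secondary structure descriptor (SSD)
#'
#' An ordered list of RSSPs describing consecutive substructures of one RNA
#' molecule. The list order is the chaining order.
#'
#' @param patterns List of [rssp()] objects.
#' @return Object of class `ssd`.
#' @export
ssd <- function(patterns) {
  stopifnot(length(patterns) >= 1L,
            all(vapply(patterns, inherits, TRUE, "rssp")))
  nms <- vapply(patterns, function(q) q$name, "")
  if (anyDuplicated(nms)) {
    stop("duplicate pattern names within an SSD: ",
         paste(nms[duplicated(nms)], collapse = ", "))
  }
  structure(list(patterns = patterns), class = "ssd")
}

#' @export
print.ssd <- function(x, ...) {
  cat("SSD with", length(x$patterns), "pattern(s):\n")
  for (q in x$patterns) print(q)
  invisible(x)
}

#' Parse a pattern description file
#'
#' Pattern files hold one or more records in file order (the chaining order for
#' SSDs). Each record is a `>name` header line, a sequence-pattern line, a
#' structure line, and optional `key=value` lines with keys `cost` and
#' `indels` overriding the defaults for that pattern. Lines starting with `#`
#' are comments.
#'
#' @param text A character vector of lines, a single string with embedded
#'   newlines, or a file path.
#' @param cost,indels Default thresholds for patterns that do not set their
#'   own.
#' @return An [ssd()] object (also for a single pattern).
#' @export
read_patterns <- function(text, cost = 0, indels = 0) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L || !startsWith(lines[1L], ">")) {
    stop("pattern file must start with a '>name' record header")
  }
  starts <- which(startsWith(lines, ">"))
  ends <- c(starts[-1L] - 1L, length(lines))
  pats <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    name <- sub("^>\\s*", "", block[1L])
    body <- block[-1L]
    kv <- grepl("=", body, fixed = TRUE)
    main <- body[!kv]
    if (length(main) < 2L) {
      stop("record '", name, "': expected a sequence line and a structure line")
    }
    if (length(main) > 2L) {
      stop("record '", name, "': too many sequence/structure lines")
    }
    k <- cost; d <- indels
    for (line in body[kv]) {
      key <- trimws(sub("=.*", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("record '", name, "': bad value in '", line, "'")
      if (key == "cost") k <- num
      else if (key == "indels") d <- num
      else stop("record '", name, "': unknown key '", key, "'")
    }
    pats[[r]] <- rssp(main[1L], main[2L], name = name, cost = k, indels = d)
  }
  ssd(pats)
}

#' Transform an RSSP for minus-strand search
#'
#' Reverses the pattern with class-wise Watson-Crick complementation and
#' reverses the structure string with brackets swapped, so that searching the
#' plus-strand text with the transformed pattern (and [complement_rules()])
#' is equivalent to searching the reverse complement of the target. Applying
#' the transformation twice returns the original pattern.
#'
#' @param q An [rssp()] object.
#' @return The transformed `rssp`.
#' @export
#' @examples
#' reverse_complement_pattern(rssp("AAGUUUC", "..(...)"))
reverse_complement_pattern <- function(q) {
  syms <- strsplit(q$pattern, "")[[1L]]
  comp_mask <- function(mask) {
    # complement the class base-wise: A<->U (bits 1,8), C<->G (bits 2,4)
    newmask <- 0L
    if (bitwAnd(mask, 1L) > 0L) newmask <- bitwOr(newmask, 8L)
    if (bitwAnd(mask, 8L) > 0L) newmask <- bitwOr(newmask, 1L)
    if (bitwAnd(mask, 2L) > 0L) newmask <- bitwOr(newmask, 4L)
    if (bitwAnd(mask, 4L) > 0L) newmask <- bitwOr(newmask, 2L)
    newmask
  }
  newsyms <- rev(vapply(vapply(syms, .class_mask, 1L), function(m) {
    .MASK2SYM[comp_mask(m)]
  }, ""))
  sch <- rev(strsplit(q$struct, "")[[1L]])
  sch <- chartr("()", ")(", paste(sch, collapse = ""))
  rssp(paste(newsyms, collapse = ""), sch,
       name = q$name, cost = q$cost, indels = q$indels)
}

#' Cost model for sequence-structure edit operations
#'
#' Non-negative costs for the edit operations. The base operations apply at
#' every pattern position: `mismatch` per match edge whose target base falls
#' outside the pattern class, `indel` per inserted or deleted base. The arc
#' penalties are charged on top, once per base pair: `arc_breaking` when both
#' partners are matched but the target bases are not complementary,
#' `arc_altering` when exactly one partner is deleted, `arc_removing` when
#' both are (so a removed arc costs `arc_removing + 2 * indel` in total).
#' Matches cost 0.
#'
#' @param mismatch,indel,arc_breaking,arc_altering,arc_removing Operation
#'   costs.
#' @return Object of class `cost_model`.
#' @export
cost_model <- function(mismatch = 1, indel = 1, arc_breaking = 1,
                       arc_altering = 1, arc_removing = 2) {
  vals <- c(mismatch = mismatch, indel = indel, arc_breaking = arc_breaking,
            arc_altering = arc_altering, arc_removing = arc_removing)
  if (any(vals < 0)) stop("operation costs must be non-negative")
  structure(as.list(vals), class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("cost model: mismatch =", x$mismatch, " indel =", x$indel,
      " arc breaking =", x$arc_breaking, " arc altering =", x$arc_altering,
      " arc removing =", x$arc_removing, "\n")
  invisible(x)
}

# ---- target sequences ----------------------------------------------------

#' Normalize a target sequence
#'
#' Uppercases and maps T to U so DNA and RNA inputs share one internal
#' alphabet. Characters outside `A C G U` are kept; they mismatch every
#' pattern class and are complementary to nothing.
#'
#' @param s Sequence string.
#' @return Normalized string.
#' @export
normalize_sequence <- function(s) {
  gsub("T", "U", toupper(s), fixed = TRUE)
}

# integer codes A=0 C=1 G=2 U=3, anything else 4
.encode_seq <- function(s) {
  codes <- match(strsplit(s, "")[[1L]], .BASES) - 1L
  codes[is.na(codes)] <- 4L
  codes
}

#' Read target sequences from a FASTA file
#'
#' Accepts DNA or RNA; sequences are normalized with [normalize_sequence()].
#'
#' @param path FASTA file path (gzip-compressed accepted).
#' @return Named character vector of sequences.
#' @export
read_target_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file ", path)
  seqs <- normalize_sequence(as.character(set))
  names(seqs) <- sub("\\s.*", "", names(set))
  seqs
}
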