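# Enhanced suffix array: construction, queries, persistence.

#' Build the enhanced suffix array of a target sequence
#'
#' Constructs the suffix array `suf` (ranks of the suffixes of `S$` in
#' ascending lexicographic order, with the terminator sorting after every
#' base), the longest-common-prefix table `lcp` (`lcp[1] = 0`, `lcp[i]` the
#' lcp length of the suffixes ranked `i-1` and `i`), and the inverse
#' permutation `isuf` with `isuf[suf[i]] = i`. The terminator is virtual: the
#' arrays have `n + 1` entries and rank the empty suffix without extending the
#' alphabet. Construction is by prefix doubling; correctness is defined by the
#' sortedness/lcp invariants, which the tests check against naive sorting.
#'
#' @param s Target sequence (string; normalized with [normalize_sequence()]),
#'   or a named length-1 character vector.
#' @return Object of class `esa` with fields `seq`, `n`, `suf`, `lcp`, `isuf`.
#' @export
#' @examples
#' esa <- build_esa("CCACCCCCCACCCACCACCCUCUU")
#' esa$suf[1]
build_esa <- function(s) {
  id <- if (!is.null(names(s))) names(s)[1L] else "seq"
  s <- normalize_sequence(as.character(s)[1L])
  if (nchar(s) < 1L) stop("cannot index an empty sequence")
  arrays <- cpp_build_sa(.encode_seq(s))
  structure(
    list(id = id, seq = s, n = nchar(s), suf = arrays$suf, lcp = arrays$lcp,
         isuf = arrays$isuf),
    class = "esa"
  )
}

#' @export
print.esa <- function(x, ...) {
  cat("enhanced suffix array of '", x$id, "' (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Maximal lcp interval at a rank
#'
#' The maximal interval of suffix-array ranks whose suffixes share a prefix of
#' length at least `depth` with the suffix of rank `i`.
#'
#' @param esa An [build_esa()] object.
#' @param i Rank (1-based).
#' @param depth Required shared prefix length (0 gives the full range).
#' @return Integer vector `c(j_start, j_end)`.
#' @export
lcp_interval_at <- function(esa, i, depth) {
  nn <- esa$n + 1L
  stopifnot(i >= 1L, i <= nn, depth >= 0L)
  if (depth == 0L) return(c(j_start = 1L, j_end = nn))
  if (depth > esa$n - esa$suf[i] + 1L) return(c(j_start = i, j_end = i))
  js <- i; je <- i
  while (js > 1L && esa$lcp[js] >= depth) js <- js - 1L
  while (je < nn && esa$lcp[je + 1L] >= depth) je <- je + 1L
  c(j_start = js, j_end = je)
}

#' Generalized suffix link
#'
#' The rank of the suffix obtained by removing the first `skip` characters of
#' the suffix of rank `i`: `isuf[suf[i] + skip]`, so that
#' `suf[suffix_link(esa, i, skip)] == suf[i] + skip`.
#'
#' @param esa An [build_esa()] object.
#' @param i Rank.
#' @param skip Number of leading characters to drop (`>= 0`).
#' @return Rank of the linked suffix.
#' @export
suffix_link <- function(esa, i, skip) {
  pos <- esa$suf[i] + skip
  if (pos > esa$n + 1L) stop("suffix link out of range: suf[i] + skip > n + 1")
  esa$isuf[pos]
}

# ---- persistence -----------------------------------------------------------

.esa_checksum <- function(esa) {
  # order-sensitive 31-bit rolling checksum over suf
  s <- 0
  for (v in as.numeric(esa$suf)) s <- (s * 131 + v) %% 2147483647
  s
}

#' Save / load an enhanced suffix array
#'
#' `save_index` writes `<prefix>.suf`, `<prefix>.lcp`, `<prefix>.isuf`
#' (little-endian 32-bit integers) plus a JSON metadata file `<prefix>.meta`
#' recording the sequence id, length, endianness, format version and a
#' checksum; `load_index` reads them back, verifying the checksum. The index
#' is built for one strand only; minus-strand searches transform the pattern
#' instead.
#'
#' @param esa An [build_esa()] object.
#' @param prefix File path prefix.
#' @param seq Optionally, the sequence for the loaded index (stored in the
#'   metadata as a FASTA path or inline when short).
#' @return `save_index`: the prefix, invisibly. `load_index`: an `esa` object.
#' @export
save_index <- function(esa, prefix) {
  stopifnot(inherits(esa, "esa"))
  for (part in c("suf", "lcp", "isuf")) {
    con <- file(paste0(prefix, ".", part), "wb")
    writeBin(as.integer(esa[[part]]), con, size = 4L, endian = "little")
    close(con)
  }
  meta <- list(format = "rsspsearch-esa", version = 1L, id = esa$id, n = esa$n,
               endian = "little", checksum = .esa_checksum(esa), seq = esa$seq)
  jsonlite::write_json(meta, paste0(prefix, ".meta"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname save_index
#' @export
load_index <- function(prefix, seq = NULL) {
  metafile <- paste0(prefix, ".meta")
  if (!file.exists(metafile)) stop("missing index metadata file ", metafile)
  meta <- jsonlite::read_json(metafile)
  if (is.null(meta$format) || meta$format != "rsspsearch-esa") {
    stop("not an index metadata file: ", metafile)
  }
  if (is.null(meta$version) || meta$version != 1L) {
    stop("unsupported index version in ", metafile)
  }
  n <- as.integer(meta$n)
  read_part <- function(part) {
    con <- file(paste0(prefix, ".", part), "rb")
    on.exit(close(con))
    readBin(con, what = "integer", n = n + 1L, size = 4L, endian = "little")
  }
  esa <- structure(
    list(id = meta$id, seq = if (is.null(seq)) meta$seq else normalize_sequence(seq),
         n = n, suf = read_part("suf"), lcp = read_part("lcp"),
         isuf = read_part("isuf")),
    class = "esa"
  )
  if (length(esa$suf) != n + 1L ||
      abs(.esa_checksum(esa) - as.numeric(meta$checksum)) > 0.5) {
    stop("index checksum mismatch for ", prefix, " (corrupted or stale files)")
  }
  esa
}
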