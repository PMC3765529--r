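Package: rsspsearch
Title: Approximate Matching of RNA Sequence-Structure Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Search nucleotide sequences for approximate matches of RNA
    sequence-structure patterns (RSSPs): IUPAC sequence patterns annotated with a
    non-crossing dot-bracket secondary structure. Matches are semi-global
    sequence-structure alignments whose edit cost (base mismatch/indel plus arc
    breaking, altering and removing operations on base pairs) stays below a
    user-defined threshold with a bounded number of indels. Provides four search
    engines over the same match semantics: a sliding-window scan with
    last-column matrix reuse, a region-wise early-stopping scan, and two
    enhanced-suffix-array engines with lcp-driven column reuse, range skipping
    and generalized suffix links. Multiple ordered patterns (secondary structure
    descriptors) are combined by global or local colinear chaining of weighted
    per-pattern matches. Includes index construction and persistence, seeded
    synthetic-data generators with planted ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
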