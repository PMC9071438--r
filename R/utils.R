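# Shared helpers: coordinate conventions, identity measures, conditions.

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Signal a validation error
#'
#' Conditions of class `crisprmob_validation_error` map to CLI exit code 2.
#' @param msg message
#' @noRd
stop_validation <- function(msg) {
  stop(structure(class = c("crisprmob_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @noRd
stop_parse <- function(msg) {
  stop(structure(class = c("crisprmob_parse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Convert 1-based inclusive intervals to 0-based half-open
#'
#' The package works in the R/GFF3 convention (1-based, inclusive) end to
#' end; these converters exist for interoperability with half-open
#' tooling and are round-trip tested.
#'
#' @param start,end integer vectors, 1-based inclusive
#' @return data.frame with columns `start` (0-based) and `end` (exclusive)
#' @export
#' @examples
#' to_zero_based(1, 10) # start 0, end 10
to_zero_based <- function(start, end) {
  stopifnot(all(end >= start))
  data.frame(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert 0-based half-open intervals to 1-based inclusive
#' @param start,end integer vectors, 0-based half-open
#' @return data.frame with 1-based inclusive `start`, `end`
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(end > start))
  data.frame(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Edge-to-edge gap between two intervals (1-based inclusive)
#'
#' Returns 0 when the intervals overlap or touch; otherwise the number of
#' bases strictly between them.
#' @param s1,e1,s2,e2 interval bounds
#' @return integer gap in bp
#' @export
interval_gap <- function(s1, e1, s2, e2) {
  lo <- pmax(s1, s2)
  hi <- pmin(e1, e2)
  ifelse(lo <= hi + 1L, 0L, lo - hi - 1L)
}

#' Reverse complement of character sequences
#' @param x character vector of DNA sequences
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Match-only global alignment identity between two sequences
#'
#' Identity used for spacer diversity: residues are paired only when they
#' match (mismatch and gap both score 0, gap open = gap extend), so
#' identity = matches / alignment columns = `100 * L / (na + nb - L)`
#' with `L` the longest-common-subsequence length. Unrelated random
#' sequences score well below 50% under this convention.
#'
#' @param a,b DNA sequences (character scalars)
#' @return percent identity in `[0, 100]`
#' @export
#' @examples
#' lcs_identity("ACGT", "ACGT") # 100
#' lcs_identity(strrep("A", 10), strrep("C", 10)) # 0
lcs_identity <- function(a, b) {
  L <- cpp_lcs_length(a, b)
  cols <- nchar(a) + nchar(b) - L
  if (cols == 0) return(100)
  100 * L / cols
}

#' Levenshtein-alignment global identity and coverage
#'
#' Identity used for repeat-vs-repeat similarity (the 85% association
#' rule and the 95/95 trusted-repeat rules): a global alignment
#' minimising unit-cost edits; identity = matches / alignment columns,
#' coverage of `b` = aligned (non-gap) positions of `b` / length of `b`.
#' A repeat differing from another only by substitutions at 4% of sites
#' therefore scores 96% identity over 100% coverage.
#'
#' @param a,b DNA sequences (character scalars)
#' @return list with `identity` and `coverage_b`, both percents
#' @export
edit_identity <- function(a, b) {
  d <- utils::adist(a, b, counts = TRUE)
  cnt <- attr(d, "counts")
  ins <- unname(cnt[1, 1, "ins"]); del <- unname(cnt[1, 1, "del"])
  sub <- unname(cnt[1, 1, "sub"])
  matches <- nchar(a) - del - sub
  alen <- nchar(a) + ins
  list(identity = if (alen > 0) 100 * matches / alen else 100,
       coverage_b = if (nchar(b) > 0) 100 * (matches + sub) / nchar(b) else 100)
}

#' Best-strand global repeat identity
#'
#' Levenshtein-alignment identity between `a` and `b`, taking the better
#' of `b` and its reverse complement.
#' @param a,b DNA sequences
#' @return percent identity
#' @export
repeat_identity <- function(a, b) {
  max(edit_identity(a, b)$identity, edit_identity(a, revcomp(b))$identity)
}

#' Test a consensus repeat against a trusted repeat (95/95-style rule)
#'
#' BLAST-style local comparison (match +1, mismatch/gap -1): the best
#' local alignment on either strand must reach `min_identity` percent
#' identity (matches / alignment columns) over at least `min_coverage`
#' percent of the trusted repeat's length. A local alignment keeps the
#' rule robust to a consensus whose boundaries over-run the repeat by a
#' column or two.
#'
#' @param consensus consensus repeat sequence
#' @param trusted trusted repeat sequence
#' @param min_identity minimum percent identity (default 95)
#' @param min_coverage minimum percent coverage of the trusted repeat
#' @return logical
#' @export
matches_trusted_repeat <- function(consensus, trusted,
                                   min_identity = 95, min_coverage = 95) {
  for (t in c(trusted, revcomp(trusted))) {
    al <- cpp_sw_align(consensus, t, match = 1, mismatch = -1, gap = -1)
    if (length(al) == 1) next
    cov <- 100 * (al$s_end - al$s_start + 1) / nchar(t)
    ident <- 100 * al$matches / al$columns
    if (ident >= min_identity && cov >= min_coverage) return(TRUE)
  }
  FALSE
}

# Random DNA of length n from the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute exactly k positions of a DNA string with different bases.
mutate_substitutions <- function(seq, k) {
  if (k == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Per-base substitution at rate `rate`.
mutate_rate <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Reciprocal overlap fraction of two 1-based inclusive intervals.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}
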