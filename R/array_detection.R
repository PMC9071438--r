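# Candidate CRISPR array detection.
#
# A CRT-like detector: exact k-mer recurrence at tandem-repeat distance
# seeds a chain of repeat units which is extended greedily in both
# directions by Hamming identity, the unit register is then widened
# column-wise under a consensus-agreement rule and finally trimmed.
# Detection runs on the forward strand only; repeat periodicity is
# strand-symmetric, so reverse-orientation arrays are detected too and
# all reported sequences are forward-strand.

#' Column-majority consensus of length-aligned repeats
#'
#' Repeats are aligned at their unit register (as produced by the
#' detector). Each column takes the majority base among the repeats long
#' enough to cover it; ties are broken by the base of the first covering
#' repeat. The consensus spans the longest repeat.
#'
#' @param repeats character vector of >= 1 repeat sequences
#' @return consensus nucleotide string
#' @export
#' @examples
#' build_consensus(c("ACGT", "ACGA", "ACGA")) # "ACGA"
#' build_consensus(c("ACGT", "ACGA"))         # tie -> "ACGT"
build_consensus <- function(repeats) {
  if (length(repeats) == 0) stop_validation("build_consensus: empty input")
  mats <- strsplit(repeats, "")
  L <- max(lengths(mats))
  out <- character(L)
  for (j in seq_len(L)) {
    col <- vapply(mats, function(ch) if (length(ch) >= j) ch[j] else NA_character_, "")
    col <- col[!is.na(col)]
    tab <- table(col)
    best <- names(tab)[tab == max(tab)]
    out[j] <- if (length(best) == 1) best else col[col %in% best][1]
  }
  paste(out, collapse = "")
}

# Hamming matches between chars[a..a+L-1] and a reference char vector.
hamming_matches <- function(chars, a, ref) {
  sum(chars[a:(a + length(ref) - 1)] == ref)
}

#' Detect candidate CRISPR arrays in a nucleotide sequence
#'
#' Reports every maximal chain of >= 2 repeat units with unit length in
#' `[min_repeat, max_repeat]`, inter-unit gap in `[min_spacer,
#' max_spacer]` and >= 80% unit-to-unit identity. Two-repeat candidates
#' are retained (they are needed for masking downstream even though they
#' are excluded from analyses). Array boundaries are widened column-wise
#' while at least two thirds of the units agree with the column majority,
#' then terminal columns with < 50% consensus agreement are trimmed.
#' Overlapping candidates are resolved by keeping the one with more
#' repeats, then the longer, then the leftmost.
#'
#' @param sequence nucleotide string (or a DNAString)
#' @param replicon_id identifier stored on each candidate
#' @param min_repeat,max_repeat repeat unit length bounds (bp)
#' @param min_spacer,max_spacer spacer length bounds (bp)
#' @param k seed word length
#' @param min_unit_identity chaining identity threshold (fraction)
#' @return list of candidate arrays; each is a list with `replicon_id`,
#'   `start`, `end`, `strand`, `repeats` and `spacers` (data.frames with
#'   start/end/seq), `consensus` and `evidence_level` (NA until curation)
#' @export
find_candidate_arrays <- function(sequence, replicon_id = "seq",
                                  min_repeat = 18L, max_repeat = 55L,
                                  min_spacer = 15L, max_spacer = 80L,
                                  k = 11L, min_unit_identity = 0.8) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  if (n < 2L * min_repeat + min_spacer) return(list())
  chars <- strsplit(sequence, "")[[1]]

  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  ord <- order(kmers, method = "radix")
  sk <- kmers[ord]
  same <- sk[-1L] == sk[-length(sk)]
  i <- ord[-length(ord)][same]
  j <- ord[-1L][same]
  d <- j - i
  keep <- d >= (min_repeat + min_spacer) & d <= (max_repeat + max_spacer)
  seeds <- data.frame(i = i[keep], j = j[keep])
  if (nrow(seeds) > 0) seeds <- seeds[order(seeds$i), , drop = FALSE]

  claimed <- rep(FALSE, n)
  candidates <- list()

  chain_next <- function(ref_start, L, from_right = TRUE) {
    # closest >= min_unit_identity occurrence of the unit at ref_start,
    # searched right (or left) of it at spacer distance; taking the
    # closest (not the best-scoring) occurrence keeps tandem decoys
    # with conserved linkers from skipping periods
    ref <- chars[ref_start:(ref_start + L - 1L)]
    if (from_right) {
      qs <- (ref_start + L + min_spacer):(ref_start + L + max_spacer)
      qs <- qs[qs + L - 1L <= n]
    } else {
      qs <- rev((ref_start - max_spacer - L):(ref_start - min_spacer - L))
      qs <- qs[qs >= 1L]
    }
    if (length(qs) == 0) return(NULL)
    m <- vapply(qs, function(q) sum(chars[q:(q + L - 1L)] == ref), 0L)
    ok <- which(m >= min_unit_identity * L)
    if (length(ok) == 0) return(NULL)
    # refine the register within a few bases of the closest hit
    near <- ok[ok <= ok[1] + 3L]
    qs[near[which.max(m[near])]]
  }

  for (s in seq_len(nrow(seeds))) {
    i0 <- seeds$i[s]; j0 <- seeds$j[s]
    # skip seeds already explained by a candidate chained through both
    # endpoints; overlap resolution keeps the best remaining candidates
    if (claimed[i0] && claimed[j0]) next
    # X-drop extension of the seed pair into a unit (tolerates isolated
    # mutations between copies); the unit length is capped at
    # d - min_spacer so the inter-unit gap stays a spacer
    d0 <- j0 - i0
    Lcap <- min(max_repeat, d0 - min_spacer)
    xdrop <- function(step) {
      # step +1 extends right of the seed, -1 extends left
      sc <- 0; best <- 0; best_x <- 0L; x <- 0L
      repeat {
        x <- x + 1L
        a <- if (step > 0) i0 + k - 1L + x else i0 - x
        b <- if (step > 0) j0 + k - 1L + x else j0 - x
        if (a < 1L || b > n || (step < 0 && a >= 1L && b < 1L)) break
        if (k + best_x + x > Lcap + 4L) break
        sc <- sc + if (chars[a] == chars[b]) 1 else -2
        if (sc > best) { best <- sc; best_x <- x }
        if (sc < best - 4) break
      }
      best_x
    }
    r <- xdrop(+1L)
    l <- xdrop(-1L)
    if (k + l + r > Lcap) { l <- min(l, Lcap - k - r) }
    u1 <- i0 - l; L <- k + l + r
    gap <- d0 - L
    if (gap < min_spacer || gap > max_spacer) next
    S <- c(u1, j0 - l)

    # greedy chain in both directions
    repeat {
      q <- chain_next(S[length(S)], L, TRUE)
      if (is.null(q)) break
      S <- c(S, q)
    }
    repeat {
      q <- chain_next(S[1], L, FALSE)
      if (is.null(q)) break
      S <- c(q, S)
    }

    # column-wise widening: extend while >= 2/3 of units agree
    agree_frac <- function(pos_vec) {
      col <- chars[pos_vec]
      max(table(col)) / length(col)
    }
    # widening (either side) grows L by 1 and shrinks every spacer by 1:
    # the inter-unit gap is diff(S) - L, which must stay >= min_spacer.
    # A single low-agreement column does not stop widening if the next
    # column agrees again (isolated mutated columns are common).
    can_widen <- function(by) L + by <= max_repeat &&
      (length(S) < 2L || all(diff(S) - (L + by) >= min_spacer))
    repeat { # right
      if (!can_widen(1L) || S[length(S)] + L > n) break
      if (agree_frac(S + L) >= 2 / 3) { L <- L + 1L; next }
      if (can_widen(2L) && S[length(S)] + L + 1L <= n &&
          agree_frac(S + L + 1L) >= 2 / 3) { L <- L + 2L; next }
      break
    }
    repeat { # left
      if (!can_widen(1L) || S[1] - 1L < 1L) break
      if (agree_frac(S - 1L) >= 2 / 3) { S <- S - 1L; L <- L + 1L; next }
      if (can_widen(2L) && S[1] - 2L >= 1L &&
          agree_frac(S - 2L) >= 2 / 3) { S <- S - 2L; L <- L + 2L; next }
      break
    }

    # trim terminal columns with < 50% consensus agreement
    reps <- substring(sequence, S, S + L - 1L)
    cons <- build_consensus(reps)
    cm <- strsplit(cons, "")[[1]]
    colagree <- vapply(seq_len(L), function(cc)
      mean(vapply(strsplit(reps, ""), function(ch) ch[cc] == cm[cc], TRUE)), 0)
    lo <- 1L; hi <- L
    while (lo <= hi && colagree[lo] < 0.5) lo <- lo + 1L
    while (hi >= lo && colagree[hi] < 0.5) hi <- hi - 1L
    if (hi - lo + 1L < min_repeat) next
    S <- S + lo - 1L
    L <- hi - lo + 1L
    if (length(S) < 2L) next

    reps <- substring(sequence, S, S + L - 1L)
    ends <- S + L - 1L
    sp_start <- ends[-length(S)] + 1L
    sp_end <- S[-1L] - 1L
    spacers <- substring(sequence, sp_start, sp_end)
    cand <- list(replicon_id = replicon_id,
                 start = S[1], end = ends[length(S)], strand = "+",
                 repeats = data.frame(start = S, end = ends, seq = reps),
                 spacers = if (length(S) > 1)
                   data.frame(start = sp_start, end = sp_end, seq = spacers)
                 else data.frame(start = integer(), end = integer(), seq = character()),
                 consensus = build_consensus(reps),
                 evidence_level = NA_integer_)
    candidates[[length(candidates) + 1L]] <- cand
    claimed[cand$start:cand$end] <- TRUE
  }

  resolve_overlaps(candidates)
}

# Keep the better of any overlapping candidate pair:
# more repeats > longer interval > leftmost.
resolve_overlaps <- function(candidates) {
  if (length(candidates) < 2) return(candidates)
  st <- vapply(candidates, `[[`, 0L, "start")
  en <- vapply(candidates, `[[`, 0L, "end")
  nr <- vapply(candidates, function(x) nrow(x$repeats), 0L)
  len <- en - st + 1L
  pref <- order(-nr, -len, st)
  keep <- logical(length(candidates))
  taken <- IRanges::IRanges()
  for (idx in pref) {
    r <- IRanges::IRanges(st[idx], en[idx])
    if (length(taken) == 0 ||
        !any(IRanges::overlapsAny(r, taken))) {
      keep[idx] <- TRUE
      taken <- c(taken, r)
    }
  }
  candidates[keep]
}

#' Detect candidate arrays across a set of replicons
#'
#' @param sequences named DNAStringSet (or named character vector)
#' @param ... passed to [find_candidate_arrays()]
#' @return flat list of candidates with `array_id` fields assigned
#' @export
detect_arrays <- function(sequences, ...) {
  seqs <- as.character(sequences)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
  out <- list()
  for (id in names(seqs)) {
    cands <- find_candidate_arrays(seqs[[id]], replicon_id = id, ...)
    out <- c(out, cands)
  }
  for (a in seq_along(out)) out[[a]]$array_id <- sprintf("cand_%04d", a)
  out
}

#' Summarise a list of candidate/curated arrays as a table
#'
#' @param arrays list of candidate arrays
#' @return data.frame with one row per array
#' @export
arrays_table <- function(arrays) {
  if (length(arrays) == 0)
    return(data.frame(array_id = character(), replicon_id = character(),
                      start = integer(), end = integer(), n_repeats = integer(),
                      consensus = character(), evidence_level = integer(),
                      status = character(), reason = character()))
  data.frame(
    array_id = vapply(arrays, function(a) a$array_id %||% NA_character_, ""),
    replicon_id = vapply(arrays, `[[`, "", "replicon_id"),
    start = vapply(arrays, `[[`, 0L, "start"),
    end = vapply(arrays, `[[`, 0L, "end"),
    n_repeats = vapply(arrays, function(a) nrow(a$repeats), 0L),
    consensus = vapply(arrays, `[[`, "", "consensus"),
    evidence_level = vapply(arrays, function(a)
      if (is.null(a$evidence_level)) NA_integer_ else as.integer(a$evidence_level), 0L),
    status = vapply(arrays, function(a) a$status %||% NA_character_, ""),
    reason = vapply(arrays, function(a) a$reason %||% NA_character_, ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
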