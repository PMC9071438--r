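# False-positive removal for candidate CRISPR arrays.
#
# Four quarantine metrics (repeat conservation, spacer conservation,
# spacer-length SEM, high-confidence ORF overlap), keep/quarantine/
# reject logic with an explicit evidence-level surrogate, two rescue
# rules (cas proximity and trusted-repeat match), a trusted-repeat
# secondary search on masked sequence, and the minimum-repeat exclusion.

#' Average repeat conservation of an array (percent)
#'
#' Mean over repeats of the fraction of consensus positions matched by
#' the repeat, where the consensus comes from [build_consensus()] and
#' positions beyond a shorter repeat's length count as mismatches.
#'
#' @param repeats character vector of >= 2 repeat sequences
#' @return percent in `[0, 100]`
#' @export
#' @examples
#' repeat_conservation(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAA")) # 96.67
repeat_conservation <- function(repeats) {
  if (length(repeats) < 2) stop_validation("repeat_conservation needs >= 2 repeats")
  cons <- strsplit(build_consensus(repeats), "")[[1]]
  L <- length(cons)
  per_repeat <- vapply(strsplit(repeats, ""), function(ch) {
    m <- sum(ch[seq_len(min(length(ch), L))] == cons[seq_len(min(length(ch), L))])
    m / L
  }, 0)
  100 * mean(per_repeat)
}

#' Mean pairwise spacer conservation (percent)
#'
#' Mean over all unordered spacer pairs of global-alignment identity
#' under the match-only scoring of [lcs_identity()] (match = 1,
#' mismatch/gap = 0, gap open = gap extend): identity = matches /
#' alignment columns. Unrelated random spacers score well below 50%
#' under this convention; near-identical linkers (iterons) score near
#' 100%.
#'
#' @param spacers character vector of >= 2 spacers
#' @return percent in `[0, 100]`
#' @export
#' @examples
#' spacer_conservation(c(strrep("A", 10), strrep("C", 10))) # 0
spacer_conservation <- function(spacers) {
  if (length(spacers) < 2) stop_validation("spacer_conservation needs >= 2 spacers")
  cpp_mean_pairwise_lcs_identity(spacers)
}

#' Standard error of the mean of spacer lengths (bp)
#'
#' Sample standard deviation (n-1 denominator) of the spacer lengths
#' divided by sqrt(n).
#'
#' @param spacers character vector of >= 2 spacers, or their lengths
#' @return SEM in bp
#' @export
#' @examples
#' spacer_length_sem(c("AAAAAAAAAA", "CCCCCCCCCC")) # 0
spacer_length_sem <- function(spacers) {
  lens <- if (is.character(spacers)) nchar(spacers) else spacers
  if (length(lens) < 2) stop_validation("spacer_length_sem needs >= 2 spacers")
  stats::sd(lens) / sqrt(length(lens))
}

#' Compute the four curation metrics for a candidate array
#'
#' With fewer than two spacers the spacer-based metrics are undefined
#' (`NA`) and the corresponding filters are treated as passed: an
#' uncomputable test cannot be failed. `orf_overlap` is TRUE when the
#' array interval overlaps any ORF with confidence >= `min_orf_conf` on
#' the same replicon.
#'
#' @param array a candidate array
#' @param orfs data.frame of ORFs (replicon_id, start, end, confidence)
#' @param min_orf_conf confidence cutoff for "high confidence" ORFs
#' @return list: repeat_conservation, spacer_conservation,
#'   spacer_length_sem, orf_overlap
#' @export
curation_metrics <- function(array, orfs = NULL, min_orf_conf = 90) {
  reps <- array$repeats$seq
  sps <- array$spacers$seq
  ov <- FALSE
  if (!is.null(orfs) && nrow(orfs) > 0) {
    o <- orfs[orfs$replicon_id == array$replicon_id & orfs$confidence >= min_orf_conf, ]
    if (nrow(o) > 0)
      ov <- any(pmax(o$start, array$start) <= pmin(o$end, array$end))
  }
  list(repeat_conservation = repeat_conservation(reps),
       spacer_conservation = if (length(sps) >= 2) spacer_conservation(sps) else NA_real_,
       spacer_length_sem = if (length(sps) >= 2) spacer_length_sem(sps) else NA_real_,
       orf_overlap = ov)
}

#' Evidence level surrogate for a candidate array
#'
#' Level 4 (high confidence, automatically kept) requires >= 4 spacers,
#' repeat conservation > 90, spacer conservation < 20, spacer-length
#' SEM < 3 and no high-confidence-ORF overlap, so the high-confidence
#' tier is a strict subset of filter-passing arrays. Level 3 = all four
#' quarantine filters pass; level 2 = at least two pass; else level 1.
#'
#' @param metrics a [curation_metrics()] result
#' @param n_spacers spacer count of the array
#' @return integer 1-4
#' @export
evidence_level <- function(metrics, n_spacers) {
  pass <- c(metrics$repeat_conservation > 70,
            is.na(metrics$spacer_conservation) || metrics$spacer_conservation < 50,
            is.na(metrics$spacer_length_sem) || metrics$spacer_length_sem < 3,
            !metrics$orf_overlap)
  if (n_spacers >= 4 && metrics$repeat_conservation > 90 &&
      !is.na(metrics$spacer_conservation) && metrics$spacer_conservation < 20 &&
      !is.na(metrics$spacer_length_sem) && metrics$spacer_length_sem < 3 &&
      !metrics$orf_overlap) return(4L)
  if (all(pass)) return(3L)
  if (sum(pass) >= 2) return(2L)
  1L
}

#' Keep/quarantine/reject a candidate array
#'
#' Evidence level 4 arrays are kept automatically. Otherwise the four
#' filters are applied in order: (i) repeat conservation > 70 (strict),
#' (ii) spacer conservation < 50, (iii) spacer-length SEM < 3, (iv) no
#' overlap with an ORF of confidence >= 90. Passing all four quarantines
#' the array (pending rescue); the first failing filter becomes the
#' rejection reason.
#'
#' @param array candidate array (used only for bookkeeping)
#' @param metrics a [curation_metrics()] result
#' @param evidence_level integer 1-4
#' @return list with `status` (kept|quarantined|rejected) and `reason`
#' @export
classify_candidate <- function(array, metrics, evidence_level) {
  if (!is.na(evidence_level) && evidence_level == 4L)
    return(list(status = "kept", reason = "evidence_level_4"))
  if (!(metrics$repeat_conservation > 70))
    return(list(status = "rejected", reason = "repeat_conservation"))
  if (!is.na(metrics$spacer_conservation) && !(metrics$spacer_conservation < 50))
    return(list(status = "rejected", reason = "spacer_conservation"))
  if (!is.na(metrics$spacer_length_sem) && !(metrics$spacer_length_sem < 3))
    return(list(status = "rejected", reason = "spacer_length_sem"))
  if (metrics$orf_overlap)
    return(list(status = "rejected", reason = "orf_overlap"))
  list(status = "quarantined", reason = "all_filters_passed")
}

#' Apply the two rescue rules to a quarantined array
#'
#' A quarantined array is rescued when a cas operon on the same replicon
#' lies within 1 kb (edge-to-edge; overlap counts as distance 0), or
#' when its consensus repeat matches any trusted repeat on either strand
#' at 95% identity over 95% of the trusted repeat's length or more. Arrays
#' that are not rescued stay quarantined and are dropped from downstream
#' analyses.
#'
#' @param array candidate array with status "quarantined"
#' @param cas_operons data.frame (replicon_id, start, end) or NULL
#' @param trusted_repeats character vector of trusted repeat sequences,
#'   or a data.frame with a `seq` column
#' @param max_cas_dist rescue distance (bp, default 1000)
#' @return list with `status` (rescued|quarantined) and `reason`
#' @export
rescue_quarantined <- function(array, cas_operons = NULL, trusted_repeats = NULL,
                               max_cas_dist = 1000) {
  if (!is.null(cas_operons) && nrow(cas_operons) > 0) {
    op <- cas_operons[cas_operons$replicon_id == array$replicon_id, ]
    if (nrow(op) > 0) {
      d <- interval_gap(op$start, op$end, array$start, array$end)
      if (any(d <= max_cas_dist))
        return(list(status = "rescued", reason = "cas_proximity"))
    }
  }
  if (!is.null(trusted_repeats)) {
    tr <- if (is.data.frame(trusted_repeats)) trusted_repeats$seq else trusted_repeats
    for (t in tr) {
      if (matches_trusted_repeat(array$consensus, t))
        return(list(status = "rescued", reason = "trusted_repeat"))
    }
  }
  list(status = "quarantined", reason = "not_rescued")
}

#' Trusted-repeat secondary search on masked sequence
#'
#' Searches each trusted repeat (both strands) against sequences in which
#' previously detected arrays have been masked, keeping hits with edit
#' distance at most floor(0.05 * repeat length), i.e. 95% identity over
#' 95% of the repeat or better. Hits on the same replicon are clustered by
#' single linkage when the gap between consecutive hits is <= 100 bp;
#' clusters with fewer than three hits are discarded, the rest become
#' candidate arrays whose inter-hit segments are the spacers.
#'
#' @param trusted_repeats character vector (or data.frame with `seq`)
#' @param sequences named DNAStringSet or character vector, already
#'   masked for every previously detected array (including 2-repeat
#'   candidates)
#' @param cluster_gap maximum gap between clustered hits (bp)
#' @return list of candidate arrays (evidence_level 3, status "kept",
#'   reason "secondary_search")
#' @export
secondary_repeat_search <- function(trusted_repeats, sequences,
                                    cluster_gap = 100L) {
  tr <- if (is.data.frame(trusted_repeats)) trusted_repeats$seq else trusted_repeats
  seqs <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
  out <- list()
  for (id in names(seqs)) {
    subject <- seqs[[id]]
    hits <- data.frame(start = integer(), end = integer())
    for (t in unique(tr)) {
      maxd <- floor(0.05 * nchar(t))
      for (pat in c(t, revcomp(t))) {
        m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                      max.mismatch = maxd, with.indels = TRUE)
        if (length(m) > 0)
          hits <- rbind(hits, data.frame(start = BiocGenerics::start(m),
                                         end = BiocGenerics::end(m)))
      }
    }
    if (nrow(hits) == 0) next
    # drop hits that touch masked (N) bases
    ok <- vapply(seq_len(nrow(hits)), function(r) {
      sub <- Biostrings::subseq(subject, hits$start[r], hits$end[r])
      Biostrings::countPattern("N", sub, fixed = TRUE) == 0 &&
        !grepl("N", as.character(sub), fixed = TRUE)
    }, TRUE)
    hits <- hits[ok, , drop = FALSE]
    if (nrow(hits) == 0) next
    # merge duplicate/overlapping hits of the same locus, then cluster
    ir <- IRanges::reduce(IRanges::IRanges(hits$start, hits$end))
    st <- BiocGenerics::start(ir); en <- BiocGenerics::end(ir)
    o <- order(st); st <- st[o]; en <- en[o]
    cl <- cumsum(c(1L, as.integer(st[-1L] - en[-length(en)] - 1L > cluster_gap)))
    for (g in unique(cl)) {
      s <- st[cl == g]; e <- en[cl == g]
      if (length(s) < 3) next
      seq_chr <- as.character(subject)
      reps <- substring(seq_chr, s, e)
      sp_s <- e[-length(e)] + 1L; sp_e <- s[-1L] - 1L
      out[[length(out) + 1L]] <- list(
        replicon_id = id, start = s[1], end = e[length(e)], strand = "+",
        repeats = data.frame(start = s, end = e, seq = reps),
        spacers = data.frame(start = sp_s, end = sp_e,
                             seq = substring(seq_chr, sp_s, sp_e)),
        consensus = build_consensus(reps),
        evidence_level = 3L, status = "kept", reason = "secondary_search")
    }
  }
  for (a in seq_along(out)) out[[a]]$array_id <- sprintf("sec_%04d", a)
  out
}

#' Exclude arrays with fewer than three repeats
#'
#' Two-repeat arrays are excluded from all analyses but must still be
#' masked before spacer matching; keep them via the `mask_set` attribute.
#'
#' @param arrays list of candidate arrays
#' @return list of arrays with >= 3 repeats; the excluded arrays are
#'   attached as `attr(, "mask_set")`
#' @export
min_repeat_filter <- function(arrays) {
  nr <- vapply(arrays, function(a) nrow(a$repeats), 0L)
  out <- arrays[nr >= 3]
  attr(out, "mask_set") <- arrays[nr < 3]
  out
}

#' Run the full curation pass over detected candidates
#'
#' Computes metrics and evidence levels, applies keep/quarantine/reject,
#' applies the rescue rules to quarantined arrays, and annotates each
#' array with `status`, `reason`, `evidence_level` and `metrics`.
#' Curation is idempotent: re-curating a curated set changes nothing.
#'
#' @param candidates list of candidate arrays from [detect_arrays()]
#' @param orfs ORF data.frame (replicon_id, start, end, confidence)
#' @param cas_operons cas operon data.frame or NULL
#' @param trusted_repeats trusted repeat sequences or NULL
#' @param min_orf_conf high-confidence ORF cutoff (default 90)
#' @return the input list, annotated; retained arrays (status kept or
#'   rescued) are flagged by `retained = TRUE`
#' @export
curate_arrays <- function(candidates, orfs = NULL, cas_operons = NULL,
                          trusted_repeats = NULL, min_orf_conf = 90) {
  lapply(candidates, function(a) {
    m <- curation_metrics(a, orfs, min_orf_conf)
    lev <- evidence_level(m, nrow(a$spacers))
    cls <- classify_candidate(a, m, lev)
    if (cls$status == "quarantined") {
      res <- rescue_quarantined(a, cas_operons, trusted_repeats)
      if (res$status == "rescued") cls <- res
    }
    a$metrics <- m
    a$evidence_level <- lev
    a$status <- cls$status
    a$reason <- cls$reason
    a$retained <- cls$status %in% c("kept", "rescued")
    a
  })
}
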