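# Spacer-protospacer matching.
#
# Masks all detected array regions (including 2-repeat candidates),
# collects spacers from typed arrays, and aligns them against plasmid
# high-confidence-ORF and virus databases with a seeded Smith-Waterman
# search (match +1, mismatch -2, gap -3, linear gaps). Significance uses
# the Karlin-Altschul expectation e = K * m * n * exp(-lambda * S) with
# m the spacer length and n the total database length.

# lambda solves (1/4) e^lambda + (3/4) e^(-2*lambda) = 1 for the +1/-2
# scheme under uniform base composition; the non-trivial root of
# x^3 - 4x^2 + 3 = 0 gives x = (3 + sqrt(21)) / 2.
KA_LAMBDA <- log((3 + sqrt(21)) / 2)
# K frozen from a one-off null calibration on shuffled sequence (random
# 35-mers vs a 200 kb random database, counting distinct hits of the
# seeded search at scores 13-14); see the methods vignette.
KA_K <- 0.7

#' Karlin-Altschul expectation value for a local alignment score
#'
#' @param score alignment score under the +1/-2/-3 unit scheme
#' @param m query (spacer) length
#' @param n total database length
#' @return expectation value
#' @export
ka_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

#' Mask detected array regions with N
#'
#' Every array interval is replaced by N; overlapping intervals are
#' unioned, all other bases are untouched and sequence lengths are
#' preserved. The mask set must include 2-repeat candidates, which are
#' otherwise excluded from analyses.
#'
#' @param sequences named DNAStringSet or character vector
#' @param arrays list of arrays (or a data.frame with replicon_id,
#'   start, end)
#' @return DNAStringSet with masked intervals
#' @export
mask_arrays <- function(sequences, arrays) {
  seqs <- Biostrings::DNAStringSet(sequences)
  df <- if (is.data.frame(arrays)) arrays else arrays_table(arrays)
  if (nrow(df) == 0) return(seqs)
  for (id in unique(df$replicon_id)) {
    if (!id %in% names(seqs)) next
    sub <- df[df$replicon_id == id, ]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
    ir <- IRanges::restrict(ir, 1L, Biostrings::width(seqs[id]))
    s <- as.character(seqs[[id]])
    for (k in seq_along(ir)) {
      a <- BiocGenerics::start(ir)[k]; b <- BiocGenerics::end(ir)[k]
      s <- paste0(substr(s, 1, a - 1), strrep("N", b - a + 1),
                  substr(s, b + 1, nchar(s)))
    }
    seqs[[id]] <- Biostrings::DNAString(s)
  }
  seqs
}

#' Collect analysis spacers from assembled loci
#'
#' Spacers from cas-linked or repeat-associated arrays are always
#' included. Spacers from orphan arrays are included only when the
#' array's consensus repeat can be typed: at least 85% identity (either
#' strand) to a subtyped entry of the repeat lookup. Duplicate spacer
#' sequences within one array are deduplicated.
#'
#' @param loci loci list from [associate_distant_arrays()]
#' @param metadata replicon metadata (for the source class)
#' @param repeat_type_lookup data.frame with `seq` and `subtype`
#'   columns; entries with NA subtype cannot type an array
#' @param min_identity typing identity threshold (percent)
#' @return data.frame of spacers: spacer_id, sequence, source_replicon,
#'   source_array, array_subtype, source_class
#' @export
collect_spacers <- function(loci, metadata, repeat_type_lookup = NULL,
                            min_identity = 85) {
  lookup <- repeat_type_lookup
  if (!is.null(lookup)) lookup <- lookup[!is.na(lookup$subtype), , drop = FALSE]
  rows <- list()
  grab <- function(a, subtype) {
    sp <- unique(a$spacers$seq)
    if (length(sp) == 0) return(NULL)
    data.frame(
      spacer_id = sprintf("%s_sp%02d", a$array_id, seq_along(sp)),
      sequence = sp,
      source_replicon = a$replicon_id,
      source_array = a$array_id,
      array_subtype = subtype,
      source_class = metadata$kind[match(a$replicon_id, metadata$replicon_id)])
  }
  for (lc in loci) {
    for (a in c(lc$arrays, lc$associated_arrays)) {
      if (lc$completeness == "orphan_array") {
        # orphan array: include only if the repeat is typeable
        subtype <- NA_character_
        if (!is.null(lookup) && nrow(lookup) > 0) {
          idents <- vapply(lookup$seq, function(t)
            repeat_identity(a$consensus, t), 0)
          if (max(idents) >= min_identity)
            subtype <- lookup$subtype[which.max(idents)]
        }
        if (is.na(subtype)) next
        rows[[length(rows) + 1L]] <- grab(a, subtype)
      } else {
        rows[[length(rows) + 1L]] <- grab(a, lc$subtype)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    spacer_id = character(), sequence = character(),
    source_replicon = character(), source_array = character(),
    array_subtype = character(), source_class = character())
  rownames(out) <- NULL
  out
}

#' Build a target database from masked plasmids restricted to
#' high-confidence ORFs
#'
#' @param masked_sequences masked plasmid DNAStringSet
#' @param orfs ORF data.frame with replicon_id, start, end, confidence
#' @param min_conf minimum ORF confidence (default 90)
#' @return object of class `target_db`
#' @export
build_orf_db <- function(masked_sequences, orfs, min_conf = 90) {
  hc <- orfs[orfs$confidence >= min_conf &
               orfs$replicon_id %in% names(masked_sequences), , drop = FALSE]
  entries <- character(0); map <- list()
  for (k in seq_len(nrow(hc))) {
    s <- as.character(Biostrings::subseq(masked_sequences[[hc$replicon_id[k]]],
                                         hc$start[k], hc$end[k]))
    entries <- c(entries, s)
    map[[k]] <- data.frame(entry = k, target_id = hc$replicon_id[k],
                           offset = hc$start[k], length = nchar(s))
  }
  structure(list(seqs = entries,
                 map = if (length(map)) do.call(rbind, map) else
                   data.frame(entry = integer(), target_id = character(),
                              offset = integer(), length = integer()),
                 target_class = "plasmid",
                 total_len = sum(nchar(entries))),
            class = "target_db")
}

#' Build a virus target database
#' @param viruses DNAStringSet of virus genomes
#' @return object of class `target_db`
#' @export
build_virus_db <- function(viruses) {
  entries <- as.character(viruses)
  structure(list(seqs = unname(entries),
                 map = data.frame(entry = seq_along(entries),
                                  target_id = names(entries),
                                  offset = 1L, length = nchar(entries)),
                 target_class = "virus",
                 total_len = sum(nchar(entries))),
            class = "target_db")
}

# k-mer index of a target_db: positions are in per-entry coordinates.
index_db <- function(db, k = 8L) {
  kmers <- character(0); entry <- integer(0); pos <- integer(0)
  for (e in seq_along(db$seqs)) {
    s <- db$seqs[e]
    n <- nchar(s)
    if (n < k) next
    p <- seq_len(n - k + 1L)
    km <- substring(s, p, p + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    kmers <- c(kmers, km[ok]); entry <- c(entry, rep(e, sum(ok))); pos <- c(pos, p[ok])
  }
  list(index = split(seq_along(kmers), kmers), entry = entry, pos = pos, k = k)
}

# Align one query (already oriented) against one db entry around a diagonal.
verify_hit <- function(query, subject_str, diag_lo, diag_hi, pad = 12L) {
  m <- nchar(query)
  w_lo <- max(1L, diag_lo + 1L - pad)
  w_hi <- min(nchar(subject_str), diag_hi + m + pad)
  if (w_hi - w_lo + 1L < 8L) return(NULL)
  win <- substr(subject_str, w_lo, w_hi)
  al <- cpp_sw_align(query, win)
  if (length(al) == 1) return(NULL)
  al$s_start <- al$s_start + w_lo - 1L
  al$s_end <- al$s_end + w_lo - 1L
  al
}

#' Match spacers against plasmid-ORF and virus databases
#'
#' Seeded local alignment of every spacer (both strands) against each
#' database under the +1/-2/-3 unit scheme; hits are retained when their
#' Karlin-Altschul expectation is at most `e_cutoff`. Self matches are
#' impossible because every detected array region is masked before the
#' databases are built.
#'
#' @param spacers data.frame from [collect_spacers()]
#' @param plasmid_orf_db a [build_orf_db()] result (or NULL)
#' @param virus_db a [build_virus_db()] result (or NULL)
#' @param e_cutoff expectation cutoff (default 0.05)
#' @param seed_k seed word length for the search (default 8)
#' @return data.frame of matches: spacer_id, target_id, target_class,
#'   identity, score, e_value, start, end, strand (target coordinates,
#'   1-based inclusive)
#' @export
match_spacers <- function(spacers, plasmid_orf_db = NULL, virus_db = NULL,
                          e_cutoff = 0.05, seed_k = 8L) {
  empty <- data.frame(spacer_id = character(), target_id = character(),
                      target_class = character(), identity = numeric(),
                      score = numeric(), e_value = numeric(),
                      start = integer(), end = integer(), strand = character())
  if (nrow(spacers) == 0) return(empty)
  out <- list()
  for (db in Filter(Negate(is.null), list(plasmid_orf_db, virus_db))) {
    if (length(db$seqs) == 0 || db$total_len == 0) next
    idx <- index_db(db, seed_k)
    for (si in seq_len(nrow(spacers))) {
      q0 <- spacers$sequence[si]
      m <- nchar(q0)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") q0 else revcomp(q0)
        p <- seq_len(max(0L, m - seed_k + 1L))
        if (length(p) == 0) next
        qk <- substring(q, p, p + seed_k - 1L)
        hit_ids <- unlist(idx$index[qk], use.names = FALSE)
        if (is.null(hit_ids) || length(hit_ids) == 0) next
        qpos <- rep(p, vapply(qk, function(w)
          length(idx$index[[w]] %||% integer(0)), 0L))
        te <- idx$entry[hit_ids]; tp <- idx$pos[hit_ids]
        diag <- tp - qpos
        for (e in unique(te)) {
          dv <- sort(unique(diag[te == e]))
          # group diagonals within 6 bp of each other
          grp <- cumsum(c(1L, as.integer(dv[-1L] - dv[-length(dv)] > 6L)))
          for (g in unique(grp)) {
            d <- dv[grp == g]
            al <- verify_hit(q, db$seqs[e], min(d), max(d))
            if (is.null(al)) next
            ev <- ka_evalue(al$score, m, db$total_len)
            if (ev > e_cutoff) next
            tgt <- substr(db$seqs[e], al$s_start, al$s_end)
            if (grepl("N", tgt, fixed = TRUE)) next
            off <- db$map$offset[db$map$entry == e][1]
            out[[length(out) + 1L]] <- data.frame(
              spacer_id = spacers$spacer_id[si],
              target_id = db$map$target_id[db$map$entry == e][1],
              target_class = db$target_class,
              identity = 100 * al$matches / al$columns,
              score = al$score, e_value = ev,
              start = off + al$s_start - 1L,
              end = off + al$s_end - 1L, strand = strand)
          }
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  # deduplicate identical loci found from several seed groups
  res <- res[!duplicated(res[, c("spacer_id", "target_id", "start", "end", "strand")]), ]
  rownames(res) <- NULL
  res
}

#' Target-class proportions of matched spacers
#'
#' Each spacer is counted at most once per category regardless of its
#' number of matches. Categories are plasmid_only, virus_only and both;
#' proportions are reported both over matched spacers and over all
#' spacers, together with the overall matched fraction.
#'
#' @param matches data.frame from [match_spacers()]
#' @param spacers data.frame from [collect_spacers()]
#' @return data.frame with category, n_spacers, prop_over_matched,
#'   prop_over_all; attributes `n_matched`, `n_total`, `matched_fraction`
#' @export
target_class_proportions <- function(matches, spacers) {
  ids <- spacers$spacer_id
  has_p <- ids %in% matches$spacer_id[matches$target_class == "plasmid"]
  has_v <- ids %in% matches$spacer_id[matches$target_class == "virus"]
  cat <- ifelse(has_p & has_v, "both",
                ifelse(has_p, "plasmid_only",
                       ifelse(has_v, "virus_only", "unmatched")))
  n_matched <- sum(cat != "unmatched")
  n_total <- length(ids)
  lv <- c("plasmid_only", "virus_only", "both")
  out <- data.frame(category = lv,
                    n_spacers = vapply(lv, function(x) sum(cat == x), 0L),
                    prop_over_matched = if (n_matched > 0)
                      vapply(lv, function(x) sum(cat == x) / n_matched, 0) else 0,
                    prop_over_all = if (n_total > 0)
                      vapply(lv, function(x) sum(cat == x) / n_total, 0) else 0)
  rownames(out) <- NULL
  attr(out, "n_matched") <- n_matched
  attr(out, "n_total") <- n_total
  attr(out, "matched_fraction") <- if (n_total > 0) n_matched / n_total else 0
  out
}

#' Conjugative vs non-conjugative targeting weights
#'
#' Each spacer with at least one plasmid match carries total weight 1,
#' split proportionally to its distinct conjugative and non-conjugative
#' plasmid targets: a spacer matching 4 conjugative and 1
#' non-conjugative plasmids contributes 0.8 and 0.2. Mobilizable
#' plasmids count as non-conjugative under the default mapping.
#'
#' @param matches data.frame from [match_spacers()] (plasmid targets)
#' @param mobility_labels named character vector, target plasmid id ->
#'   mobility label
#' @param conjugative_labels labels counted as conjugative
#' @return list with `weights` (per spacer: weight_conjugative,
#'   weight_non_conjugative) and `totals` (named numeric length 2)
#' @export
conjugative_weighting <- function(matches, mobility_labels,
                                  conjugative_labels = "conjugative") {
  pm <- matches[matches$target_class == "plasmid", , drop = FALSE]
  if (nrow(pm) == 0)
    return(list(weights = data.frame(spacer_id = character(),
                                     weight_conjugative = numeric(),
                                     weight_non_conjugative = numeric()),
                totals = c(conjugative = 0, non_conjugative = 0)))
  unlabeled <- setdiff(unique(pm$target_id), names(mobility_labels))
  if (length(unlabeled) > 0)
    stop_validation(paste0("unlabeled target plasmid(s): ",
                           paste(unlabeled, collapse = ", ")))
  rows <- lapply(split(pm, pm$spacer_id), function(sub) {
    tgts <- unique(sub$target_id)
    conj <- sum(mobility_labels[tgts] %in% conjugative_labels)
    data.frame(spacer_id = sub$spacer_id[1],
               weight_conjugative = conj / length(tgts),
               weight_non_conjugative = (length(tgts) - conj) / length(tgts))
  })
  w <- do.call(rbind, rows)
  rownames(w) <- NULL
  list(weights = w,
       totals = c(conjugative = sum(w$weight_conjugative),
                  non_conjugative = sum(w$weight_non_conjugative)))
}
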