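# Assembly of CRISPR-Cas loci from curated arrays and cas operons.
#
# Arrays closer than 10 kb (edge-to-edge, strict) to the nearest cas
# operon on the same replicon are linked to it; unlinked arrays are
# associated with an operon when their consensus repeat is at least 85%
# identical (either strand) to the repeat of an operon-adjacent array.
# Loci are classified complete / orphan_array / orphan_cas.

#' Link curated arrays to cas operons by distance
#'
#' An array links to the nearest operon on the same replicon when the
#' edge-to-edge distance is strictly below `max_dist` (overlap counts as
#' 0). Each array links to at most one operon (nearest; tie broken by
#' the leftmost operon). Operons with no linked array become orphan_cas
#' loci; arrays with no linkable operon are left for
#' [associate_distant_arrays()].
#'
#' @param arrays list of retained curated arrays
#' @param operons data.frame (operon_id, replicon_id, start, end,
#'   subtype, genes)
#' @param max_dist linkage cutoff in bp (default 10000, strict `<`)
#' @return list of loci; each locus is a list with `locus_id`,
#'   `replicon_id`, `operon` (row or NULL), `arrays` (list),
#'   `associated_arrays` (list), `subtype`, `completeness`
#' @export
link_arrays_to_operons <- function(arrays, operons, max_dist = 10000) {
  loci <- list()
  if (!is.null(operons) && nrow(operons) > 0) {
    for (k in seq_len(nrow(operons))) {
      op <- operons[k, ]
      loci[[op$operon_id]] <- list(
        locus_id = paste0("locus_", op$operon_id),
        replicon_id = op$replicon_id, operon = op,
        arrays = list(), associated_arrays = list(),
        subtype = op$subtype, completeness = "orphan_cas")
    }
  }
  unlinked <- list()
  for (a in arrays) {
    best <- NULL; best_d <- Inf
    if (!is.null(operons) && nrow(operons) > 0) {
      same <- operons[operons$replicon_id == a$replicon_id, , drop = FALSE]
      if (nrow(same) > 0) {
        d <- interval_gap(same$start, same$end, a$start, a$end)
        ok <- which(d < max_dist)
        if (length(ok) > 0) {
          dmin <- min(d[ok])
          cand <- same[ok[d[ok] == dmin], , drop = FALSE]
          best <- cand[which.min(cand$start), ] # tie -> leftmost operon
          best_d <- dmin
        }
      }
    }
    if (!is.null(best)) {
      a$link <- "linked"
      a$array_subtype <- best$subtype
      loci[[best$operon_id]]$arrays <- c(loci[[best$operon_id]]$arrays, list(a))
      loci[[best$operon_id]]$completeness <- "complete"
    } else {
      unlinked <- c(unlinked, list(a))
    }
  }
  attr(loci, "unlinked") <- unlinked
  loci
}

#' Associate distant arrays to operons by repeat similarity
#'
#' An unlinked array is associated with (typed by, but not merged into)
#' an operon's locus when its consensus repeat is at least 85% identical
#' (either strand, inclusive) to the consensus repeat of an array
#' adjacent to that operon. The best-identity operon wins; ties prefer
#' an operon on the same replicon, then the leftmost. Arrays that cannot
#' be associated become orphan_array loci.
#'
#' @param unlinked_arrays list of arrays not linked by distance (by
#'   default taken from `attr(loci, "unlinked")`)
#' @param loci loci list from [link_arrays_to_operons()]
#' @param min_identity percent identity threshold (default 85, inclusive)
#' @return updated loci list; orphan arrays appended as their own loci
#' @export
associate_distant_arrays <- function(unlinked_arrays = NULL, loci,
                                     min_identity = 85) {
  if (is.null(unlinked_arrays)) unlinked_arrays <- attr(loci, "unlinked")
  adjacent <- list()
  for (lc in loci) {
    if (length(lc$arrays) > 0) {
      for (a in lc$arrays)
        adjacent[[length(adjacent) + 1L]] <- list(
          operon_id = lc$operon$operon_id, replicon_id = lc$replicon_id,
          operon_start = lc$operon$start, consensus = a$consensus,
          subtype = lc$subtype)
    }
  }
  orphan_n <- 0L
  for (a in unlinked_arrays) {
    best <- NULL
    if (length(adjacent) > 0) {
      idents <- vapply(adjacent, function(ad)
        repeat_identity(a$consensus, ad$consensus), 0)
      ok <- which(idents >= min_identity)
      if (length(ok) > 0) {
        top <- max(idents[ok])
        cand <- ok[idents[ok] == top]
        same_rep <- cand[vapply(adjacent[cand], function(ad)
          ad$replicon_id == a$replicon_id, TRUE)]
        pick <- if (length(same_rep) > 0) same_rep else cand
        pos <- vapply(adjacent[pick], function(ad) as.numeric(ad$operon_start), 0)
        best <- adjacent[[pick[which.min(pos)]]]
      }
    }
    if (!is.null(best)) {
      a$link <- "associated"
      a$array_subtype <- best$subtype
      loci[[best$operon_id]]$associated_arrays <-
        c(loci[[best$operon_id]]$associated_arrays, list(a))
    } else {
      orphan_n <- orphan_n + 1L
      a$link <- "orphan"
      a$array_subtype <- NA_character_
      id <- sprintf("orphan_array_%03d", orphan_n)
      loci[[id]] <- list(locus_id = id, replicon_id = a$replicon_id,
                         operon = NULL, arrays = list(a),
                         associated_arrays = list(),
                         subtype = NA_character_,
                         completeness = "orphan_array")
    }
  }
  attr(loci, "unlinked") <- NULL
  loci
}

#' Per-replicon summary of assembled loci
#'
#' Counts loci by completeness class per replicon, flags multi-system
#' replicons (>= 2 operon-bearing loci) with their subtype combination,
#' and reports per-locus presence of the adaptation module (both cas1
#' and cas2 in the operon gene list).
#'
#' @param loci loci list from [associate_distant_arrays()]
#' @return list with `loci` (one row per locus: locus_id, replicon_id,
#'   completeness, subtype, n_arrays, has_adaptation) and `replicons`
#'   (per-replicon counts, multi_system flag, subtype_combination)
#' @export
summarize_loci <- function(loci) {
  if (length(loci) == 0)
    return(list(loci = data.frame(), replicons = data.frame()))
  rows <- lapply(loci, function(lc) {
    genes <- if (!is.null(lc$operon)) strsplit(lc$operon$genes, ",")[[1]] else character()
    data.frame(locus_id = lc$locus_id, replicon_id = lc$replicon_id,
               completeness = lc$completeness,
               subtype = if (is.null(lc$subtype) || is.na(lc$subtype))
                 "untyped" else lc$subtype,
               n_arrays = length(lc$arrays) + length(lc$associated_arrays),
               has_adaptation = all(c("cas1", "cas2") %in% genes) &&
                 length(genes) > 0)
  })
  ldf <- do.call(rbind, rows)
  rownames(ldf) <- NULL
  reps <- unique(ldf$replicon_id)
  rdf <- do.call(rbind, lapply(reps, function(r) {
    sub <- ldf[ldf$replicon_id == r, ]
    op_bearing <- sub[sub$completeness %in% c("complete", "orphan_cas"), ]
    multi <- nrow(op_bearing) >= 2
    combo <- if (multi) {
      types <- sort(unique(sub("([IVX]+)[-._].*", "\\1", op_bearing$subtype)))
      paste(types, collapse = "+")
    } else NA_character_
    data.frame(replicon_id = r,
               complete = sum(sub$completeness == "complete"),
               orphan_array = sum(sub$completeness == "orphan_array"),
               orphan_cas = sum(sub$completeness == "orphan_cas"),
               n_arrays = sum(sub$n_arrays),
               multi_system = multi, subtype_combination = combo)
  }))
  rownames(rdf) <- NULL
  list(loci = ldf, replicons = rdf)
}
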