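# Directed plasmid-plasmid targeting network and taxonomic confinement.

#' Build directed plasmid-plasmid targeting pairs
#'
#' One pair per ordered (source plasmid, target plasmid) connected by at
#' least one spacer-protospacer match; cross-targeting plasmids yield
#' two separate pairs. `n_spacer_matches` counts the distinct spacers
#' linking the pair. Self-targeting (source = target) is excluded from
#' the pairs and reported via `attr(, "self_targets")`.
#'
#' @param matches data.frame from [match_spacers()], plasmid targets
#' @param spacers data.frame from [collect_spacers()] giving each
#'   spacer's source replicon (only plasmid-sourced spacers form pairs)
#' @return data.frame: source_plasmid, target_plasmid, n_spacer_matches
#' @export
build_pairs <- function(matches, spacers) {
  pm <- matches[matches$target_class == "plasmid", , drop = FALSE]
  pm$source <- spacers$source_replicon[match(pm$spacer_id, spacers$spacer_id)]
  pm$source_class <- spacers$source_class[match(pm$spacer_id, spacers$spacer_id)]
  pm <- pm[!is.na(pm$source) & pm$source_class == "plasmid", , drop = FALSE]
  self <- pm[pm$source == pm$target_id, , drop = FALSE]
  pm <- pm[pm$source != pm$target_id, , drop = FALSE]
  if (nrow(pm) == 0) {
    out <- data.frame(source_plasmid = character(),
                      target_plasmid = character(),
                      n_spacer_matches = integer())
  } else {
    key <- paste(pm$source, pm$target_id, sep = "\r")
    agg <- tapply(pm$spacer_id, key, function(x) length(unique(x)))
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    out <- data.frame(source_plasmid = vapply(parts, `[`, "", 1),
                      target_plasmid = vapply(parts, `[`, "", 2),
                      n_spacer_matches = as.integer(agg))
    out <- out[order(out$source_plasmid, out$target_plasmid), ]
    rownames(out) <- NULL
  }
  attr(out, "self_targets") <- self
  out
}

# Most specific rank at which two host taxonomies agree, walking
# species -> domain; vectorised over pairs. Agreement must be
# hierarchically consistent (same species implies same genus, ...).
confinement_ranks <- function(tax_a, tax_b) {
  A <- vapply(TAX_RANKS, function(r) {
    a <- tax_a[[r]]; b <- tax_b[[r]]
    !is.na(a) & !is.na(b) & a == b
  }, logical(nrow(tax_a)))
  A <- matrix(A, ncol = length(TAX_RANKS),
              dimnames = list(NULL, TAX_RANKS))
  prefix <- A[, 1]
  depth <- as.integer(prefix)
  for (r in 2:ncol(A)) {
    bad <- A[, r] & !prefix
    if (any(bad))
      stop_validation(sprintf(
        "inconsistent taxonomy: hosts agree at %s but not at a broader rank",
        TAX_RANKS[r]))
    prefix <- prefix & A[, r]
    depth <- depth + as.integer(prefix)
  }
  ifelse(depth == 0, "none", TAX_RANKS[pmax(depth, 1L)])
}

#' Taxonomic confinement of targeting pairs
#'
#' Each pair is assigned to the most specific host-taxonomy rank shared
#' by both plasmids' hosts ("exclusively within rank r" = agree at r but
#' at no more specific rank); each pair is counted once. Pairs whose
#' plasmids lack taxonomy are dropped and counted separately.
#'
#' @param pairs data.frame from [build_pairs()]
#' @param taxonomy data.frame with replicon_id and the rank columns
#'   domain..species
#' @return data.frame: rank, observed_count, observed_pct (over
#'   assignable pairs); attribute `n_dropped`
#' @export
taxonomic_confinement <- function(pairs, taxonomy) {
  ranks_out <- c(rev(TAX_RANKS), "none") # species first
  counts <- setNames(integer(length(ranks_out)), ranks_out)
  dropped <- 0L
  if (nrow(pairs) > 0) {
    ia <- match(pairs$source_plasmid, taxonomy$replicon_id)
    ib <- match(pairs$target_plasmid, taxonomy$replicon_id)
    ok <- !is.na(ia) & !is.na(ib)
    dropped <- sum(!ok)
    if (any(ok)) {
      rk <- confinement_ranks(taxonomy[ia[ok], TAX_RANKS, drop = FALSE],
                              taxonomy[ib[ok], TAX_RANKS, drop = FALSE])
      tab <- table(factor(rk, levels = ranks_out))
      counts[names(tab)] <- as.integer(tab)
    }
  }
  n <- sum(counts)
  out <- data.frame(rank = ranks_out, observed_count = as.integer(counts),
                    observed_pct = if (n > 0) 100 * as.integer(counts) / n else 0)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Permutation null for taxonomic confinement
#'
#' Permutes the plasmid-to-taxonomy assignment among the plasmids
#' participating in pairs (so a plasmid appearing in many pairs keeps
#' one coherent permuted taxonomy), recomputes confinement for each
#' permutation and reports the per-rank medians. A per-endpoint mode
#' (labels shuffled over pair endpoints independently) is provided
#' behind `unit = "endpoint"`.
#'
#' @param pairs data.frame from [build_pairs()]
#' @param taxonomy taxonomy data.frame
#' @param n_perm number of permutations (default 100)
#' @param seed RNG seed
#' @param unit `"plasmid"` (default) or `"endpoint"`
#' @return data.frame: rank, observed_count, observed_pct, null_median;
#'   attribute `perm_counts` (n_perm x ranks matrix)
#' @export
permuted_confinement <- function(pairs, taxonomy, n_perm = 100, seed = 1L,
                                 unit = c("plasmid", "endpoint")) {
  unit <- match.arg(unit)
  obs <- taxonomic_confinement(pairs, taxonomy)
  plasmids <- unique(c(pairs$source_plasmid, pairs$target_plasmid))
  plasmids <- plasmids[plasmids %in% taxonomy$replicon_id]
  set.seed(seed)
  perm_mat <- matrix(0L, n_perm, nrow(obs),
                     dimnames = list(NULL, obs$rank))
  for (b in seq_len(n_perm)) {
    if (unit == "plasmid") {
      perm <- setNames(sample(plasmids), plasmids)
      tax_b <- taxonomy
      idx <- match(plasmids, taxonomy$replicon_id)
      tax_b[idx, TAX_RANKS] <- taxonomy[match(perm, taxonomy$replicon_id), TAX_RANKS]
      cb <- taxonomic_confinement(pairs, tax_b)
    } else {
      endpoints <- c(pairs$source_plasmid, pairs$target_plasmid)
      shuffled <- sample(endpoints)
      k <- nrow(pairs)
      pp <- data.frame(source_plasmid = shuffled[seq_len(k)],
                       target_plasmid = shuffled[k + seq_len(k)],
                       n_spacer_matches = pairs$n_spacer_matches)
      cb <- taxonomic_confinement(pp, taxonomy)
    }
    perm_mat[b, ] <- cb$observed_count
  }
  obs$null_median <- apply(perm_mat, 2, stats::median)
  attr(obs, "perm_counts") <- perm_mat
  obs
}

#' Export the targeting network
#'
#' Writes a directed graph with node attributes (host order,
#' has_crispr_cas) and edge weight = n_spacer_matches as GraphML and as
#' an edge-list TSV.
#'
#' @param pairs data.frame from [build_pairs()]
#' @param metadata replicon metadata (order column used when present)
#' @param graphml_path,tsv_path output paths (NULL to skip)
#' @param crispr_replicons character vector of replicon ids carrying
#'   CRISPR-Cas (sets the has_crispr_cas node flag)
#' @return the igraph object, invisibly
#' @export
export_network <- function(pairs, metadata = NULL, graphml_path = NULL,
                           tsv_path = NULL, crispr_replicons = character()) {
  nodes <- unique(c(pairs$source_plasmid, pairs$target_plasmid))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(pairs) > 0)
      data.frame(from = pairs$source_plasmid, to = pairs$target_plasmid,
                 weight = pairs$n_spacer_matches)
    else data.frame(from = character(), to = character(), weight = numeric()),
    directed = TRUE,
    vertices = if (length(nodes) > 0) data.frame(name = nodes) else NULL)
  if (length(nodes) > 0) {
    ord <- if (!is.null(metadata) && "order" %in% names(metadata))
      metadata$order[match(nodes, metadata$replicon_id)] else NA_character_
    igraph::V(g)$host_order <- ifelse(is.na(ord), "unknown", ord)
    igraph::V(g)$has_crispr_cas <- nodes %in% crispr_replicons
  }
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(tsv_path)) {
    el <- data.frame(source = pairs$source_plasmid,
                     target = pairs$target_plasmid,
                     weight = pairs$n_spacer_matches)
    write_tsv(el, tsv_path)
  }
  invisible(g)
}

#' Read a targeting network back from GraphML
#'
#' @param graphml_path path written by [export_network()]
#' @return data.frame with source_plasmid, target_plasmid,
#'   n_spacer_matches
#' @export
read_network <- function(graphml_path) {
  g <- igraph::read_graph(graphml_path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) == 0)
    return(data.frame(source_plasmid = character(),
                      target_plasmid = character(),
                      n_spacer_matches = integer()))
  out <- data.frame(source_plasmid = el$from, target_plasmid = el$to,
                    n_spacer_matches = as.integer(el$weight))
  out[order(out$source_plasmid, out$target_plasmid), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
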