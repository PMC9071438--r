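# Prevalence and enrichment statistics.
#
# Per-replicon and per-Mbp prevalence of CRISPR-Cas locus categories,
# a binary indicator-value (IndVal) analysis with a group-equalized
# variant and permutation p-values, and 2x2 Fisher enrichment.

#' Prevalence of locus categories per replicon class
#'
#' For each completeness category (complete, orphan_array, orphan_cas)
#' and each replicon class (plasmid, chromosome): the fraction of
#' replicons carrying at least one locus of the category, and the mean
#' per-Mbp count, i.e. mean over replicons of count * 1e6 / length_bp.
#'
#' @param locus_summary result of [summarize_loci()] (its `loci` element
#'   is used), or a data.frame with replicon_id and completeness
#' @param metadata replicon metadata with replicon_id, kind, length_bp
#' @return data.frame: category, kind, n_replicons, n_loci,
#'   frac_replicons_with, mean_per_mbp
#' @export
prevalence <- function(locus_summary, metadata) {
  ldf <- if (is.list(locus_summary) && !is.data.frame(locus_summary))
    locus_summary$loci else locus_summary
  if (any(metadata$length_bp <= 0))
    stop_validation("prevalence: zero-length replicon in metadata")
  cats <- c("complete", "orphan_array", "orphan_cas")
  kinds <- unique(metadata$kind)
  out <- list()
  for (cat in cats) {
    for (kd in kinds) {
      md <- metadata[metadata$kind == kd, ]
      counts <- vapply(md$replicon_id, function(r)
        if (is.null(ldf) || nrow(ldf) == 0) 0L else
          sum(ldf$replicon_id == r & ldf$completeness == cat), 0L)
      out[[length(out) + 1L]] <- data.frame(
        category = cat, kind = kd, n_replicons = nrow(md),
        n_loci = sum(counts),
        frac_replicons_with = mean(counts >= 1),
        mean_per_mbp = mean(counts * 1e6 / md$length_bp))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

indval_stat <- function(presence, groups, mode) {
  # presence: 0/1 vector; groups: factor; returns per-group stat vector
  glev <- levels(groups)
  a_k <- vapply(glev, function(g) sum(presence[groups == g]), 0)
  n_k <- vapply(glev, function(g) sum(groups == g), 0)
  B <- ifelse(n_k > 0, a_k / n_k, 0)
  if (sum(a_k) == 0) return(setNames(rep(0, length(glev)), glev))
  A <- if (mode == "standard") a_k / sum(a_k) else {
    rel <- a_k / n_k
    if (sum(rel) == 0) rep(0, length(glev)) else rel / sum(rel)
  }
  setNames(sqrt(A * B), glev)
}

#' Binary indicator-value (IndVal) analysis with permutation p-values
#'
#' For each subtype (column) and group k with `a_k` presences among
#' `n_k` replicons: fidelity `B_k = a_k / n_k`; specificity
#' `A_k = a_k / sum(a)` (standard) or `A_k = (a_k/n_k) / sum_g(a_g/n_g)`
#' (group-equalized, which controls for unequal group sizes). The
#' statistic is `sqrt(A_k * B_k)` for the best group. Significance is
#' assessed by permuting the row group labels:
#' `p = (1 + count(permuted stat >= observed)) / (n_perm + 1)`,
#' then Bonferroni-adjusted over subtypes.
#' With `exhaustive = TRUE` (two groups only) all distinct label
#' assignments are enumerated and `p = #{stat >= observed} / n_total`
#' (the identity assignment guarantees p > 0).
#'
#' @param matrix binary presence matrix, rows = replicons, columns =
#'   subtypes (counts are collapsed to presence/absence)
#' @param groups group label per row (2 or more groups)
#' @param mode `"standard"` or `"group_equalized"`
#' @param n_perm number of permutations (default 9999)
#' @param seed integer RNG seed for the permutations
#' @param alpha significance level applied to the adjusted p
#' @param exhaustive enumerate all distinct assignments (2 groups only)
#' @return data.frame: subtype, group, stat, p_value, p_adjusted,
#'   significant
#' @export
indval <- function(matrix, groups, mode = c("standard", "group_equalized"),
                   n_perm = 9999, seed = 1L, alpha = 0.05,
                   exhaustive = FALSE) {
  mode <- match.arg(mode)
  X <- as.matrix(matrix)
  X <- (X > 0) + 0L
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_validation("indval needs >= 2 groups")
  if (nrow(X) != length(groups)) stop_validation("groups must match matrix rows")
  J <- ncol(X)
  obs <- lapply(seq_len(J), function(j) indval_stat(X[, j], groups, mode))
  obs_best <- vapply(obs, max, 0)
  obs_group <- vapply(obs, function(s) names(s)[which.max(s)], "")

  if (exhaustive) {
    if (nlevels(groups) != 2) stop_validation("exhaustive mode supports 2 groups")
    n1 <- sum(groups == levels(groups)[1])
    combos <- utils::combn(length(groups), n1)
    cnt <- numeric(J)
    for (cix in seq_len(ncol(combos))) {
      g <- factor(rep(levels(groups)[2], length(groups)), levels = levels(groups))
      g[combos[, cix]] <- levels(groups)[1]
      for (j in seq_len(J))
        if (max(indval_stat(X[, j], g, mode)) >= obs_best[j] - 1e-12)
          cnt[j] <- cnt[j] + 1
    }
    p <- cnt / ncol(combos)
  } else {
    set.seed(seed)
    cnt <- numeric(J)
    for (b in seq_len(n_perm)) {
      g <- groups[sample.int(length(groups))]
      for (j in seq_len(J))
        if (max(indval_stat(X[, j], g, mode)) >= obs_best[j] - 1e-12)
          cnt[j] <- cnt[j] + 1
    }
    p <- (1 + cnt) / (n_perm + 1)
  }
  p[colSums(X) == 0] <- 1
  obs_best[colSums(X) == 0] <- 0
  padj <- pmin(1, p * J)
  data.frame(subtype = colnames(X) %||% sprintf("subtype_%d", seq_len(J)),
             group = obs_group, stat = obs_best, p_value = p,
             p_adjusted = padj, significant = padj <= alpha)
}

#' 2x2 enrichment test (sample odds ratio + Fisher exact p)
#'
#' Reports the sample (cross-product) odds ratio `(a*d)/(b*c)` and the
#' two-sided exact p-value from the hypergeometric distribution of the
#' table. A zero row or column margin leaves the odds ratio undefined
#' (`NA`) with a flag.
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @return list: odds_ratio, p_value, flag (NA or "zero_margin")
#' @export
#' @examples
#' enrichment_2x2(matrix(c(10, 10, 10, 10), 2)) # OR = 1
enrichment_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop_validation("enrichment_2x2 expects a 2x2 matrix of non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = NA_real_, flag = "zero_margin"))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, flag = NA_character_)
}

#' Build a presence matrix of subtypes per replicon
#'
#' @param locus_summary result of [summarize_loci()]
#' @param metadata replicon metadata (all replicons become rows)
#' @param use one of "complete", "operon_bearing" (complete + orphan_cas)
#' @return list with `matrix` (0/1, rows = replicons) and `groups`
#'   (replicon kind per row)
#' @export
presence_matrix <- function(locus_summary, metadata,
                            use = c("operon_bearing", "complete")) {
  use <- match.arg(use)
  ldf <- locus_summary$loci
  keep <- if (use == "complete") "complete" else c("complete", "orphan_cas")
  ldf <- ldf[ldf$completeness %in% keep & ldf$subtype != "untyped", , drop = FALSE]
  subtypes <- sort(unique(ldf$subtype))
  M <- matrix(0L, nrow(metadata), max(1L, length(subtypes)),
              dimnames = list(metadata$replicon_id,
                              if (length(subtypes)) subtypes else "none"))
  for (r in seq_len(nrow(ldf))) {
    M[ldf$replicon_id[r], ldf$subtype[r]] <- 1L
  }
  list(matrix = M, groups = metadata$kind)
}
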