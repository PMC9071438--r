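# Independent brute-force oracles and fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the optimised implementations.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Majority consensus with the first-repeat tie rule, written column by
# column with plain loops.
oracle_consensus <- function(reps) {
  mats <- strsplit(reps, "")
  L <- max(vapply(mats, length, 0L))
  out <- character(L)
  for (j in seq_len(L)) {
    col <- character(0)
    for (m in mats) if (length(m) >= j) col <- c(col, m[j])
    counts <- table(col)
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) == 1) out[j] <- winners
    else {
      for (m in mats) if (length(m) >= j && m[j] %in% winners) { out[j] <- m[j]; break }
    }
  }
  paste(out, collapse = "")
}

# Explicit double loop over repeats x consensus columns; columns beyond
# a repeat's end are mismatches.
oracle_repeat_conservation <- function(reps) {
  cons <- strsplit(oracle_consensus(reps), "")[[1]]
  tot <- 0
  for (rp in strsplit(reps, "")) {
    m <- 0
    for (j in seq_along(cons)) {
      if (j <= length(rp) && rp[j] == cons[j]) m <- m + 1
    }
    tot <- tot + m / length(cons)
  }
  100 * tot / length(reps)
}

# Plain dynamic-programming LCS.
oracle_lcs <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) return(0L)
  D <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1, j + 1] <- if (x[i] == y[j]) D[i, j] + 1L
    else max(D[i, j + 1], D[i + 1, j])
  }
  D[n + 1, m + 1]
}

oracle_spacer_conservation <- function(spacers) {
  tot <- 0; k <- 0
  for (i in seq_along(spacers)) for (j in seq_along(spacers)) {
    if (j <= i) next
    L <- oracle_lcs(spacers[i], spacers[j])
    cols <- nchar(spacers[i]) + nchar(spacers[j]) - L
    tot <- tot + if (cols > 0) 100 * L / cols else 100
    k <- k + 1
  }
  tot / k
}

oracle_sem <- function(lens) {
  n <- length(lens)
  mu <- sum(lens) / n
  sqrt(sum((lens - mu)^2) / (n - 1)) / sqrt(n)
}

# Two-sided Fisher p by summing hypergeometric point masses no larger
# than that of the observed table (margins fixed).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exhaustive binary IndVal permutation p for two groups, enumerating
# every distinct placement of the group-1 labels with explicit loops.
oracle_indval_exhaustive <- function(presence, groups, mode = "standard") {
  glev <- unique(groups)
  stat_of <- function(g) {
    best <- 0
    for (k in glev) {
      a_k <- sum(presence[g == k]); n_k <- sum(g == k)
      if (sum(presence) == 0) next
      B <- a_k / n_k
      A <- if (mode == "standard") a_k / sum(presence)
      else {
        rel <- c(sum(presence[g == glev[1]]) / sum(g == glev[1]),
                 sum(presence[g == glev[2]]) / sum(g == glev[2]))
        (a_k / n_k) / sum(rel)
      }
      s <- sqrt(A * B)
      if (s > best) best <- s
    }
    best
  }
  obs <- stat_of(groups)
  n1 <- sum(groups == glev[1])
  combos <- utils::combn(length(groups), n1)
  cnt <- 0
  for (cix in seq_len(ncol(combos))) {
    g <- rep(glev[2], length(groups))
    g[combos[, cix]] <- glev[1]
    if (stat_of(g) >= obs - 1e-12) cnt <- cnt + 1
  }
  list(stat = obs, p = cnt / ncol(combos))
}

# Build a candidate-array object from repeat/spacer sequences with
# consistent coordinates starting at `start`.
make_array <- function(repeats, spacers, replicon_id = "r1", start = 101L,
                       array_id = "arr1") {
  stopifnot(length(spacers) == length(repeats) - 1)
  rs <- integer(length(repeats)); re <- integer(length(repeats))
  ss <- integer(length(spacers)); se <- integer(length(spacers))
  pos <- start
  for (i in seq_along(repeats)) {
    rs[i] <- pos; re[i] <- pos + nchar(repeats[i]) - 1L
    pos <- re[i] + 1L
    if (i <= length(spacers)) {
      ss[i] <- pos; se[i] <- pos + nchar(spacers[i]) - 1L
      pos <- se[i] + 1L
    }
  }
  list(array_id = array_id, replicon_id = replicon_id,
       start = rs[1], end = re[length(repeats)], strand = "+",
       repeats = data.frame(start = rs, end = re, seq = repeats),
       spacers = if (length(spacers))
         data.frame(start = ss, end = se, seq = spacers)
       else data.frame(start = integer(), end = integer(), seq = character()),
       consensus = build_consensus(repeats),
       evidence_level = NA_integer_)
}

# One small community shared across test files (cached per session).
small_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_plasmids = 10, n_chromosomes = 3,
                              n_true_arrays = 15, n_decoys = 8,
                              n_protospacers = 20, rng_seed = 42)
      cache <<- generate_community(cfg)
    }
    cache
  }
})
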