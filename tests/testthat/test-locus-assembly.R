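op_row <- function(id, replicon, start, end, subtype = "I-E",
                   genes = "cas3,cas7,cas5") {
  data.frame(operon_id = id, replicon_id = replicon, start = start, end = end,
             subtype = subtype, genes = genes,
             has_adaptation = grepl("cas1", genes))
}

test_that("10 kb linkage boundary is strict", {
  set.seed(31)
  arr <- make_array(replicate(3, rand_dna(30)), replicate(2, rand_dna(35)),
                    start = 1000L)
  gap_to <- function(gap) op_row("op1", "r1", arr$end + gap + 1, arr$end + gap + 4000)
  # edge-to-edge 9999 bp: linked
  loci <- link_arrays_to_operons(list(arr), gap_to(9999))
  expect_equal(loci[["op1"]]$completeness, "complete")
  expect_length(attr(loci, "unlinked"), 0)
  # exactly 10000 bp: not linked
  loci2 <- link_arrays_to_operons(list(arr), gap_to(10000))
  expect_equal(loci2[["op1"]]$completeness, "orphan_cas")
  expect_length(attr(loci2, "unlinked"), 1)
})

test_that("equidistant arrays link to the leftmost operon", {
  arr <- make_array(replicate(3, rand_dna(30)), replicate(2, rand_dna(35)),
                    start = 20000L)
  ops <- rbind(op_row("left", "r1", arr$start - 3000, arr$start - 501),
               op_row("right", "r1", arr$end + 501, arr$end + 3000))
  loci <- link_arrays_to_operons(list(arr), ops)
  expect_equal(loci[["left"]]$completeness, "complete")
  expect_equal(loci[["right"]]$completeness, "orphan_cas")
})

test_that("planted operons at 5 kb and 15 kb: only the 5 kb array links", {
  a5 <- make_array(replicate(3, rand_dna(30)), replicate(2, rand_dna(35)),
                   start = 1000L, array_id = "a5")
  a15 <- make_array(replicate(3, rand_dna(30)), replicate(2, rand_dna(35)),
                    replicon_id = "r2", start = 1000L, array_id = "a15")
  ops <- rbind(op_row("op5", "r1", a5$end + 5001, a5$end + 9000),
               op_row("op15", "r2", a15$end + 15001, a15$end + 19000))
  loci <- link_arrays_to_operons(list(a5, a15), ops)
  expect_equal(loci[["op5"]]$completeness, "complete")
  expect_equal(loci[["op15"]]$completeness, "orphan_cas")
  expect_equal(attr(loci, "unlinked")[[1]]$array_id, "a15")
})

test_that("repeat-identity association is inclusive at 85%", {
  set.seed(32)
  # adjacent repeat: 20 bp; 17/20 matches = 85.0% exactly
  adj <- rand_dna(20)
  ch <- strsplit(adj, "")[[1]]
  mk_sub <- function(pos) {
    x <- ch
    for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
    paste(x, collapse = "")
  }
  linked <- make_array(rep(adj, 3), replicate(2, rand_dna(30)), start = 1000L,
                       array_id = "adj")
  ops <- op_row("op1", "r1", linked$end + 100, linked$end + 4000, subtype = "IV-A3")
  at85 <- make_array(rep(mk_sub(c(3, 9, 15)), 3), replicate(2, rand_dna(30)),
                     replicon_id = "r9", start = 1000L, array_id = "at85")
  below <- make_array(rep(mk_sub(c(3, 6, 9, 15)), 3), replicate(2, rand_dna(30)),
                      replicon_id = "r9", start = 5000L, array_id = "below")
  loci <- link_arrays_to_operons(list(linked), ops)
  loci <- associate_distant_arrays(list(at85, below), loci)
  expect_equal(repeat_identity(at85$consensus, linked$consensus), 85)
  expect_lt(repeat_identity(below$consensus, linked$consensus), 85)
  expect_length(loci[["op1"]]$associated_arrays, 1)
  expect_equal(loci[["op1"]]$associated_arrays[[1]]$array_id, "at85")
  sm <- summarize_loci(loci)
  expect_equal(sm$loci$completeness[sm$loci$locus_id == "orphan_array_001"],
               "orphan_array")
})

test_that("association without operon-adjacent arrays changes nothing", {
  arr <- make_array(replicate(3, rand_dna(30)), replicate(2, rand_dna(35)))
  loci <- link_arrays_to_operons(list(), data.frame())
  out <- associate_distant_arrays(list(arr), loci)
  expect_equal(vapply(out, `[[`, "", "completeness"), c(orphan_array_001 = "orphan_array"))
})

test_that("summaries count classes, adaptation and multi-system labels", {
  set.seed(33)
  arr1 <- make_array(replicate(3, rand_dna(30)), replicate(2, rand_dna(35)),
                     start = 1000L, array_id = "a1")
  orphan <- make_array(replicate(3, rand_dna(30)), replicate(2, rand_dna(35)),
                       start = 30000L, array_id = "a2")
  ops <- rbind(op_row("opI", "r1", arr1$end + 200, arr1$end + 5000,
                      subtype = "I-E", genes = "cas3,cas8e,cas7,cas5"),
               op_row("opIV", "r1", 60000, 64000, subtype = "IV-A3",
                      genes = "cas1,cas2,csf1,csf2"))
  loci <- link_arrays_to_operons(list(arr1, orphan), ops)
  loci <- associate_distant_arrays(loci = loci)
  sm <- summarize_loci(loci)
  r1 <- sm$replicons[sm$replicons$replicon_id == "r1", ]
  expect_equal(r1$complete, 1)
  expect_equal(r1$orphan_array, 1)
  expect_equal(r1$orphan_cas, 1)
  expect_true(r1$multi_system)
  expect_equal(r1$subtype_combination, "I+IV")
  expect_false(sm$loci$has_adaptation[sm$loci$locus_id == "locus_opI"])
  expect_true(sm$loci$has_adaptation[sm$loci$locus_id == "locus_opIV"])
})

test_that("every array and operon lands in exactly one locus role", {
  com <- small_community()
  cands <- detect_arrays(com$sequences)
  cur <- curate_arrays(cands, com$orfs, com$cas_operons, com$trusted_repeats)
  ret <- min_repeat_filter(Filter(function(a) isTRUE(a$retained), cur))
  loci <- associate_distant_arrays(
    loci = link_arrays_to_operons(ret, com$cas_operons))
  ids <- unlist(lapply(loci, function(lc)
    c(vapply(lc$arrays, `[[`, "", "array_id"),
      vapply(lc$associated_arrays, `[[`, "", "array_id"))))
  expect_setequal(ids, vapply(ret, `[[`, "", "array_id"))
  expect_false(any(duplicated(ids)))
  op_ids <- unlist(lapply(loci, function(lc)
    if (!is.null(lc$operon)) lc$operon$operon_id else character()))
  expect_setequal(op_ids, com$cas_operons$operon_id)
})

test_that("raising the linkage cutoff never unlinks arrays", {
  com <- small_community()
  cands <- detect_arrays(com$sequences)
  cur <- curate_arrays(cands, com$orfs, com$cas_operons, com$trusted_repeats)
  ret <- min_repeat_filter(Filter(function(a) isTRUE(a$retained), cur))
  n_linked <- function(d) {
    loci <- link_arrays_to_operons(ret, com$cas_operons, max_dist = d)
    sum(vapply(loci, function(lc) length(lc$arrays), 0L))
  }
  counts <- vapply(c(1000, 5000, 10000, 20000, 50000), n_linked, 0L)
  expect_true(all(diff(counts) >= 0))
})
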