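test_that("masking replaces array intervals with N and preserves length", {
  set.seed(51)
  s <- Biostrings::DNAStringSet(c(r1 = rand_dna(500), r2 = rand_dna(300)))
  arrs <- data.frame(replicon_id = c("r1", "r1", "r2"),
                     start = c(101, 150, 50), end = c(160, 220, 80))
  m <- mask_arrays(s, arrs)
  expect_equal(Biostrings::width(m), Biostrings::width(s))
  c1 <- as.character(m[["r1"]])
  # overlapping intervals are unioned: one N block 101..220
  expect_equal(substr(c1, 101, 220), strrep("N", 120))
  expect_equal(substr(c1, 1, 100), substr(as.character(s[["r1"]]), 1, 100))
  expect_false(grepl("N", substr(c1, 221, 500)))
  # no arrays -> identity
  expect_identical(as.character(mask_arrays(s, data.frame())),
                   as.character(s))
})

test_that("spacer collection honours the typed-repeat inclusion rule", {
  set.seed(52)
  adj <- rand_dna(30)
  linked <- make_array(rep(adj, 3), replicate(2, rand_dna(35)), array_id = "lk")
  ops <- data.frame(operon_id = "op1", replicon_id = "r1",
                    start = linked$end + 100, end = linked$end + 4000,
                    subtype = "I-E", genes = "cas3", has_adaptation = FALSE)
  # orphan array with an untypeable repeat
  orphan_bad <- make_array(replicate(3, rand_dna(30))[c(1, 1, 1)],
                           replicate(2, rand_dna(35)),
                           replicon_id = "r2", array_id = "ob")
  # orphan array whose repeat matches the lookup at ~90%
  lk_seq <- rand_dna(30)
  ch <- strsplit(lk_seq, "")[[1]]
  for (p in c(7, 14, 21)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  orphan_ok <- make_array(rep(paste(ch, collapse = ""), 3),
                          replicate(2, rand_dna(35)),
                          replicon_id = "r3", array_id = "og")
  md <- data.frame(replicon_id = c("r1", "r2", "r3"),
                   kind = "plasmid", length_bp = 1e5)
  lookup <- data.frame(repeat_id = c("t1", "t2"),
                       seq = c(lk_seq, rand_dna(30)),
                       subtype = c("V-A", NA))
  loci <- link_arrays_to_operons(list(linked), ops)
  loci <- associate_distant_arrays(list(orphan_bad, orphan_ok), loci)
  sp <- collect_spacers(loci, md, lookup)
  expect_setequal(unique(sp$source_array), c("lk", "og"))
  expect_equal(sum(sp$source_array == "lk"), 2)
  expect_equal(unique(sp$array_subtype[sp$source_array == "lk"]), "I-E")
  expect_equal(unique(sp$array_subtype[sp$source_array == "og"]), "V-A")
  # duplicate spacer sequences within an array are deduplicated
  dup <- make_array(rep(adj, 4), c("ACGTACGTACGTACGTACGTACGTA",
                                   "ACGTACGTACGTACGTACGTACGTA",
                                   rand_dna(30)),
                    array_id = "dp")
  loci2 <- link_arrays_to_operons(list(dup), ops)
  sp2 <- collect_spacers(loci2, md, lookup)
  expect_equal(sum(sp2$source_array == "dp"), 2)
})

test_that("an exact planted protospacer is matched and random absence is not", {
  set.seed(53)
  sp_seq <- rand_dna(32)
  db_seq <- paste0(rand_dna(50000), sp_seq, rand_dna(50000))
  vdb <- build_virus_db(Biostrings::DNAStringSet(c(v1 = db_seq)))
  spacers <- data.frame(spacer_id = c("s1", "s2"),
                        sequence = c(sp_seq, rand_dna(32)),
                        source_replicon = "p0", source_array = "a0",
                        array_subtype = "I-E", source_class = "plasmid")
  mt <- match_spacers(spacers, virus_db = vdb)
  hit <- mt[mt$spacer_id == "s1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 50001)
  expect_equal(hit$end, 50032)
  expect_equal(hit$identity, 100)
  expect_lt(hit$e_value, 1e-10)
  # reverse-complement planting is found on the minus strand
  db2 <- paste0(rand_dna(20000), revcomp(sp_seq), rand_dna(20000))
  mt2 <- match_spacers(spacers[1, ],
                       virus_db = build_virus_db(
                         Biostrings::DNAStringSet(c(v2 = db2))))
  expect_equal(mt2$strand, "-")
  expect_equal(mt2$start, 20001)
})

test_that("matches never intersect masked intervals", {
  set.seed(54)
  sp_seq <- rand_dna(32)
  raw <- paste0(rand_dna(2000), sp_seq, rand_dna(2000))
  masked <- mask_arrays(Biostrings::DNAStringSet(c(v1 = raw)),
                        data.frame(replicon_id = "v1", start = 2001, end = 2032))
  spacers <- data.frame(spacer_id = "s1", sequence = sp_seq,
                        source_replicon = "p0", source_array = "a0",
                        array_subtype = "I-E", source_class = "plasmid")
  mt <- match_spacers(spacers, virus_db = build_virus_db(masked))
  expect_equal(nrow(mt), 0)
})

test_that("count-once rule is independent of database duplication", {
  set.seed(55)
  sp_seq <- rand_dna(34)
  entry <- paste0(rand_dna(3000), sp_seq, rand_dna(3000))
  md <- data.frame(replicon_id = c("pA", "pB"), kind = "plasmid", length_bp = 1e5)
  orfs <- data.frame(orf_id = c("o1", "o2"), replicon_id = c("pA", "pB"),
                     start = 1, end = nchar(entry), strand = "+", confidence = 95)
  seqs <- Biostrings::DNAStringSet(c(pA = entry, pB = entry))
  spacers <- data.frame(spacer_id = "s1", sequence = sp_seq,
                        source_replicon = "p0", source_array = "a0",
                        array_subtype = "I-E", source_class = "plasmid")
  db1 <- build_orf_db(seqs[1], orfs[1, ])
  db2 <- build_orf_db(seqs, orfs)
  p1 <- target_class_proportions(match_spacers(spacers, db1), spacers)
  p2 <- target_class_proportions(match_spacers(spacers, db2), spacers)
  expect_equal(attr(p1, "n_matched"), 1L)
  expect_equal(attr(p2, "n_matched"), 1L)
  expect_equal(p1$n_spacers, p2$n_spacers)
})

test_that("target-class proportions use both denominators", {
  spacers <- data.frame(spacer_id = c("s1", "s2", "s3", "s4"),
                        sequence = "A", source_replicon = "p0",
                        source_array = "a0", array_subtype = "I-E",
                        source_class = "plasmid")
  matches <- data.frame(
    spacer_id = c("s1", "s1", "s1", "s2", "s3", "s3"),
    target_id = c("pA", "pB", "pC", "v1", "pA", "v1"),
    target_class = c("plasmid", "plasmid", "plasmid", "virus",
                     "plasmid", "virus"),
    identity = 100, score = 30, e_value = 1e-9,
    start = 1, end = 30, strand = "+")
  pr <- target_class_proportions(matches, spacers)
  expect_equal(pr$n_spacers[pr$category == "plasmid_only"], 1L) # s1 counted once
  expect_equal(pr$n_spacers[pr$category == "virus_only"], 1L)
  expect_equal(pr$n_spacers[pr$category == "both"], 1L)
  expect_equal(attr(pr, "matched_fraction"), 3 / 4)
  expect_equal(pr$prop_over_matched, rep(1 / 3, 3))
  expect_equal(pr$prop_over_all, rep(1 / 4, 3))
})

test_that("conjugative weighting follows the worked example exactly", {
  mob <- c(pA = "conjugative", pB = "conjugative", pC = "conjugative",
           pD = "conjugative", pE = "non_mobilizable", pF = "mobilizable")
  mk <- function(spacer, targets) data.frame(
    spacer_id = spacer, target_id = targets, target_class = "plasmid",
    identity = 100, score = 30, e_value = 1e-9, start = 1, end = 30,
    strand = "+")
  # 4 conjugative + 1 non-conjugative -> 0.8 / 0.2
  w <- conjugative_weighting(mk("s1", c("pA", "pB", "pC", "pD", "pE")), mob)
  expect_identical(w$weights$weight_conjugative, 0.8)
  expect_identical(w$weights$weight_non_conjugative, 0.2)
  # single conjugative target -> 1.0 / 0.0
  w2 <- conjugative_weighting(mk("s2", "pA"), mob)
  expect_identical(unname(w2$totals), c(1, 0))
  # 2 + 2 -> 0.5 each; mobilizable counts as non-conjugative
  w3 <- conjugative_weighting(mk("s3", c("pA", "pB", "pE", "pF")), mob)
  expect_identical(unname(w3$totals), c(0.5, 0.5))
  # weights always sum to 1 per spacer
  set.seed(56)
  for (i in 1:20) {
    tg <- sample(names(mob), sample(1:6, 1))
    wi <- conjugative_weighting(mk("sx", tg), mob)
    expect_equal(wi$weights$weight_conjugative +
                   wi$weights$weight_non_conjugative, 1)
  }
  expect_error(conjugative_weighting(mk("s4", "unknown_plasmid"), mob),
               "unknown_plasmid")
})
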