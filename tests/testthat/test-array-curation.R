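test_that("worked metric examples evaluate as documented", {
  expect_equal(repeat_conservation(rep("ACGTACGT", 4)), 100)
  expect_equal(repeat_conservation(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAA")),
               (100 + 100 + 90) / 3)
  expect_equal(spacer_conservation(rep("ACGTACGT", 3)), 100)
  expect_equal(spacer_conservation(c(strrep("A", 10), strrep("C", 10))), 0)
  expect_equal(spacer_length_sem(c("AAAA", "CCCC", "GGGG")), 0)
  expect_equal(spacer_length_sem(c(30, 32, 34)), 2 / sqrt(3))
  expect_equal(spacer_length_sem(c(10, 40, 80)), sd(c(10, 40, 80)) / sqrt(3))
  expect_error(repeat_conservation("ACGT"), ">= 2")
  expect_error(spacer_conservation("ACGT"), ">= 2")
})

test_that("metrics equal brute-force oracles on random arrays", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    reps <- replicate(n, rand_dna(sample(20:47, 1)))
    sps <- replicate(max(2, n - 1), rand_dna(sample(25:45, 1)))
    expect_equal(repeat_conservation(reps), oracle_repeat_conservation(reps),
                 tolerance = 1e-9)
    expect_equal(spacer_conservation(sps), oracle_spacer_conservation(sps),
                 tolerance = 1e-9)
    expect_equal(spacer_length_sem(sps), oracle_sem(nchar(sps)),
                 tolerance = 1e-9)
  }
})

test_that("classification applies strict thresholds in order", {
  arr <- make_array(replicate(4, rand_dna(30)), replicate(3, rand_dna(35)))
  m <- list(repeat_conservation = 96.7, spacer_conservation = 12,
            spacer_length_sem = 1.2, orf_overlap = FALSE)
  expect_equal(classify_candidate(arr, m, 3L)$status, "quarantined")
  # boundary: exactly 70 is not > 70
  m2 <- m; m2$repeat_conservation <- 70
  r2 <- classify_candidate(arr, m2, 3L)
  expect_equal(r2$status, "rejected")
  expect_equal(r2$reason, "repeat_conservation")
  # level 4 is kept regardless of metrics
  expect_equal(classify_candidate(arr, m2, 4L)$status, "kept")
  # first failing filter wins (order i-iv)
  m3 <- m; m3$spacer_conservation <- 55; m3$spacer_length_sem <- 10
  expect_equal(classify_candidate(arr, m3, 3L)$reason, "spacer_conservation")
  m4 <- m; m4$spacer_length_sem <- 3
  expect_equal(classify_candidate(arr, m4, 3L)$reason, "spacer_length_sem")
  m5 <- m; m5$orf_overlap <- TRUE
  expect_equal(classify_candidate(arr, m5, 3L)$reason, "orf_overlap")
  # undefined spacer metrics pass their filters
  m6 <- list(repeat_conservation = 80, spacer_conservation = NA_real_,
             spacer_length_sem = NA_real_, orf_overlap = FALSE)
  expect_equal(classify_candidate(arr, m6, 3L)$status, "quarantined")
})

test_that("rescue rules: cas proximity and trusted repeat", {
  set.seed(22)
  arr <- make_array(replicate(4, rand_dna(30)), replicate(3, rand_dna(35)),
                    start = 5000L)
  # cas gene 800 bp away (edge to edge)
  ops <- data.frame(replicon_id = "r1",
                    start = arr$end + 801, end = arr$end + 3000)
  r <- rescue_quarantined(arr, ops, NULL)
  expect_equal(r$status, "rescued"); expect_equal(r$reason, "cas_proximity")
  # 1001 bp away: not within 1 kb
  ops2 <- data.frame(replicon_id = "r1",
                     start = arr$end + 1002, end = arr$end + 3000)
  expect_equal(rescue_quarantined(arr, ops2, NULL)$status, "quarantined")
  # overlapping operon counts as distance zero
  ops3 <- data.frame(replicon_id = "r1", start = arr$start + 10, end = arr$end + 500)
  expect_equal(rescue_quarantined(arr, ops3, NULL)$status, "rescued")
  # cas on another replicon does not rescue
  ops4 <- data.frame(replicon_id = "r2", start = arr$end + 100, end = arr$end + 300)
  expect_equal(rescue_quarantined(arr, ops4, NULL)$status, "quarantined")

  # trusted repeat at ~96% identity rescues; at 90% it does not
  cons <- arr$consensus
  ch <- strsplit(cons, "")[[1]]
  t96 <- ch; t96[15] <- setdiff(c("A", "C", "G", "T"), t96[15])[1]
  r2 <- rescue_quarantined(arr, NULL, paste(t96, collapse = ""))
  expect_equal(r2$status, "rescued"); expect_equal(r2$reason, "trusted_repeat")
  t90 <- ch
  for (p in c(4, 12, 21)) t90[p] <- setdiff(c("A", "C", "G", "T"), t90[p])[1]
  expect_equal(rescue_quarantined(arr, NULL, paste(t90, collapse = ""))$status,
               "quarantined")
})

test_that("secondary search clusters hits and enforces the repeat minimum", {
  set.seed(23)
  tr <- rand_dna(30)
  # three exact copies with 40 bp gaps -> one 3-repeat array
  s1 <- paste0(rand_dna(500), tr, rand_dna(40), tr, rand_dna(40), tr, rand_dna(500))
  out <- secondary_repeat_search(tr, Biostrings::DNAStringSet(c(x = s1)))
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]$repeats), 3)
  expect_equal(nrow(out[[1]]$spacers), 2)
  expect_equal(out[[1]]$start, 501)

  # two hits 150 bp apart -> two singleton clusters, both discarded
  s2 <- paste0(rand_dna(500), tr, rand_dna(150), tr, rand_dna(500))
  expect_length(secondary_repeat_search(tr, Biostrings::DNAStringSet(c(x = s2))), 0)

  # hits inside masked intervals are excluded
  s3 <- paste0(rand_dna(500), strrep("N", 110),
               tr, rand_dna(40), tr, rand_dna(40), tr, rand_dna(500))
  masked <- mask_arrays(Biostrings::DNAStringSet(c(x = s3)),
                        data.frame(replicon_id = "x", start = 611,
                                   end = 610 + 3 * 30 + 80))
  expect_length(secondary_repeat_search(tr, masked), 0)
})

test_that("minimum-repeat filter keeps the mask set aside", {
  a2 <- make_array(replicate(2, rand_dna(25)), replicate(1, rand_dna(30)))
  a3 <- make_array(replicate(3, rand_dna(25)), replicate(2, rand_dna(30)),
                   array_id = "arr3")
  out <- min_repeat_filter(list(a2, a3))
  expect_length(out, 1)
  expect_equal(out[[1]]$array_id, "arr3")
  expect_length(attr(out, "mask_set"), 1)
  expect_equal(attr(out, "mask_set")[[1]]$array_id, "arr1")
  expect_length(min_repeat_filter(list()), 0)
})

test_that("curation is idempotent", {
  com <- small_community()
  cands <- detect_arrays(com$sequences)
  c1 <- curate_arrays(cands, com$orfs, com$cas_operons, com$trusted_repeats)
  c2 <- curate_arrays(c1, com$orfs, com$cas_operons, com$trusted_repeats)
  expect_equal(arrays_table(c1), arrays_table(c2))
})
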