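mk_matches <- function(spacer_id, target_id) {
  data.frame(spacer_id = spacer_id, target_id = target_id,
             target_class = "plasmid", identity = 100, score = 30,
             e_value = 1e-9, start = 1, end = 30, strand = "+")
}
mk_spacers <- function(ids, sources) {
  data.frame(spacer_id = ids, sequence = "A", source_replicon = sources,
             source_array = "a", array_subtype = "I-E",
             source_class = "plasmid")
}
mk_tax <- function(ids, species, genus = NULL, family = NULL) {
  n <- length(ids)
  if (is.null(genus)) genus <- sub("_s.*", "", species)
  if (is.null(family)) family <- sub("_g.*", "", genus)
  data.frame(replicon_id = ids, domain = "d1", phylum = "ph1", class = "cl1",
             order = "or1", family = family, genus = genus, species = species)
}

test_that("pairs aggregate distinct spacers; cross-targeting gives two pairs", {
  sp <- mk_spacers(c("s1", "s2", "s3", "s4"), c("A", "A", "A", "B"))
  mt <- mk_matches(c("s1", "s2", "s3", "s3", "s4"),
                   c("B", "B", "B", "C", "A"))
  pr <- build_pairs(mt, sp)
  expect_equal(nrow(pr), 3)
  ab <- pr[pr$source_plasmid == "A" & pr$target_plasmid == "B", ]
  expect_equal(ab$n_spacer_matches, 3L)
  # A -> B and B -> A are distinct ordered pairs
  expect_equal(nrow(pr[pr$source_plasmid == "B" & pr$target_plasmid == "A", ]), 1)
  # self-targeting excluded but reported
  mt2 <- rbind(mt, mk_matches("s1", "A"))
  pr2 <- build_pairs(mt2, sp)
  expect_equal(nrow(pr2), 3)
  expect_equal(nrow(attr(pr2, "self_targets")), 1)
})

test_that("confinement assigns the most specific shared rank once per pair", {
  tax <- mk_tax(c("A", "B", "C", "D"),
                species = c("f1_g1_s1", "f1_g1_s1", "f1_g2_s3", "f9_g9_s9"))
  pairs <- data.frame(source_plasmid = c("A", "A", "A"),
                      target_plasmid = c("B", "C", "D"),
                      n_spacer_matches = 1L)
  cf <- taxonomic_confinement(pairs, tax)
  expect_equal(cf$observed_count[cf$rank == "species"], 1L) # A-B
  expect_equal(cf$observed_count[cf$rank == "family"], 1L)  # A-C: genus differs
  expect_equal(cf$observed_count[cf$rank == "genus"], 0L)
  expect_equal(cf$observed_count[cf$rank == "order"], 1L)   # A-D
  expect_equal(sum(cf$observed_count), nrow(pairs))         # partition
  expect_equal(sum(cf$observed_pct), 100)

  # all pairs same species -> 100% species-confined
  tax2 <- mk_tax(c("A", "B", "C"), species = rep("f1_g1_s1", 3))
  pairs2 <- data.frame(source_plasmid = c("A", "B"),
                       target_plasmid = c("B", "C"), n_spacer_matches = 1L)
  cf2 <- taxonomic_confinement(pairs2, tax2)
  expect_equal(cf2$observed_pct[cf2$rank == "species"], 100)

  # inconsistent hierarchy errors out
  bad <- tax
  bad$genus <- c("g1", "g2", "g3", "g4") # same species, different genus
  expect_error(taxonomic_confinement(pairs, bad), "inconsistent")

  # unknown-host pairs are dropped and counted
  pairs3 <- rbind(pairs, data.frame(source_plasmid = "A",
                                    target_plasmid = "Zmissing",
                                    n_spacer_matches = 1L))
  cf3 <- taxonomic_confinement(pairs3, tax)
  expect_equal(attr(cf3, "n_dropped"), 1L)
  expect_equal(sum(cf3$observed_count), 3L)
})

test_that("permutation null is seeded and collapses for uniform labels", {
  set.seed(61)
  ids <- sprintf("P%02d", 1:12)
  tax <- mk_tax(ids, species = sample(c("f1_g1_s1", "f1_g1_s2", "f2_g3_s4"),
                                      12, replace = TRUE))
  pairs <- data.frame(source_plasmid = sample(ids, 20, replace = TRUE),
                      target_plasmid = sample(ids, 20, replace = TRUE),
                      n_spacer_matches = 1L)
  pairs <- pairs[pairs$source_plasmid != pairs$target_plasmid, ]
  r1 <- permuted_confinement(pairs, tax, n_perm = 25, seed = 7)
  r2 <- permuted_confinement(pairs, tax, n_perm = 25, seed = 7)
  expect_identical(r1$null_median, r2$null_median)
  expect_identical(attr(r1, "perm_counts"), attr(r2, "perm_counts"))
  r3 <- permuted_confinement(pairs, tax, n_perm = 25, seed = 8)
  expect_false(identical(attr(r1, "perm_counts"), attr(r3, "perm_counts")))

  # identical taxonomy everywhere: permutation cannot change anything
  tax_same <- mk_tax(ids, species = rep("f1_g1_s1", 12))
  r4 <- permuted_confinement(pairs, tax_same, n_perm = 10, seed = 1)
  expect_equal(r4$null_median, as.numeric(r4$observed_count))

  # endpoint mode runs and keeps the pair count fixed
  r5 <- permuted_confinement(pairs, tax, n_perm = 10, seed = 1,
                             unit = "endpoint")
  expect_equal(sum(r5$observed_count), nrow(pairs))
  expect_true(all(rowSums(attr(r5, "perm_counts")) == nrow(pairs)))
})

test_that("adding a pair never decreases cumulative rank counts", {
  ids <- sprintf("P%02d", 1:8)
  set.seed(62)
  tax <- mk_tax(ids, species = sample(c("f1_g1_s1", "f1_g2_s2", "f3_g4_s5"),
                                      8, replace = TRUE))
  pairs <- data.frame(source_plasmid = ids[1:4], target_plasmid = ids[5:8],
                      n_spacer_matches = 1L)
  cum_counts <- function(p) rev(cumsum(rev(
    taxonomic_confinement(p, tax)$observed_count)))
  base <- cum_counts(pairs)
  more <- rbind(pairs, data.frame(source_plasmid = "P01",
                                  target_plasmid = "P03",
                                  n_spacer_matches = 1L))
  expect_true(all(cum_counts(more) >= base))
})

test_that("network export round-trips through GraphML", {
  pairs <- data.frame(source_plasmid = c("A", "B"),
                      target_plasmid = c("B", "A"),
                      n_spacer_matches = c(3L, 1L))
  md <- data.frame(replicon_id = c("A", "B", "C"), kind = "plasmid",
                   order = c("or1", "or2", "or1"), length_bp = 1e5)
  gml <- tempfile(fileext = ".graphml"); tsv <- tempfile(fileext = ".tsv")
  g <- export_network(pairs, md, gml, tsv, crispr_replicons = "A")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::V(g)["A"]$has_crispr_cas)
  back <- read_network(gml)
  expect_equal(back, pairs[order(pairs$source_plasmid), ],
               ignore_attr = TRUE)
  el <- read_tsv_checked(tsv, c("source", "target", "weight"))
  expect_equal(nrow(el), 2)
  # empty network still writes valid files
  empty <- pairs[0, ]
  g0 <- export_network(empty, md, gml, tsv)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(nrow(read_network(gml)), 0)
})
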