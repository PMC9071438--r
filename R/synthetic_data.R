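# Synthetic plasmid-community generator with planted ground truth.
#
# Emulates the statistical structure the detection/curation pipeline
# assumes: i.i.d. uniform ACGT background (so unplanted repeats are not
# detectable at default parameters), true CRISPR arrays that pass all
# four curation filters by construction, decoys that each violate
# exactly one named filter, cas operons at controlled distances,
# protospacers planted with an exact mismatch count, and
# taxonomy/mobility labels with known truth.

#' Configuration for the synthetic plasmid community
#'
#' Defaults describe a desk-scale community: modest plasmids and a few
#' larger chromosomes, repeat/spacer geometry in the canonical CRISPR
#' range, and a 70/30 plasmid/virus protospacer target split.
#'
#' @param n_plasmids number of plasmid replicons
#' @param n_chromosomes number of chromosome replicons
#' @param plasmid_len_range,chrom_len_range replicon length ranges (bp)
#' @param n_true_arrays number of planted true CRISPR arrays
#' @param n_decoys number of planted false-positive decoys
#' @param repeat_len_range direct-repeat length range (bp)
#' @param spacer_len_range spacer length range (bp)
#' @param n_repeats_range repeats per planted array
#' @param repeat_mut_rate per-base substitution probability applied to
#'   each repeat copy relative to the array's master repeat
#' @param n_protospacers number of planted protospacers
#' @param protospacer_mismatches substitutions per planted protospacer copy
#' @param protospacer_plasmid_fraction fraction of protospacers planted
#'   into plasmid ORFs (the rest go into virus genomes)
#' @param n_viruses,virus_len_range virus genome count and length range
#' @param cas_fraction fraction of true arrays given a cas operon nearby
#' @param cas_distance_range edge-to-edge gap range between array and its
#'   cas operon (bp)
#' @param n_orphan_cas standalone cas operons with no nearby array
#' @param orfs_per_kb mean ORF density on replicons
#' @param orf_len_range ORF length range (bp)
#' @param hc_orf_fraction fraction of ORFs given confidence >= 90
#' @param taxonomy_depth number of ranks, domain..species (fixed at 7)
#' @param mobility_fractions named proportions for conjugative,
#'   mobilizable, non_mobilizable; must sum to 1
#' @param rng_seed integer seed; identical config + seed reproduces the
#'   community byte for byte
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_plasmids = 40,
                             n_chromosomes = 10,
                             plasmid_len_range = c(8000L, 25000L),
                             chrom_len_range = c(50000L, 100000L),
                             n_true_arrays = 60,
                             n_decoys = 30,
                             repeat_len_range = c(23L, 47L),
                             spacer_len_range = c(25L, 45L),
                             n_repeats_range = c(4L, 8L),
                             repeat_mut_rate = 0.02,
                             n_protospacers = 60,
                             protospacer_mismatches = 1L,
                             protospacer_plasmid_fraction = 0.7,
                             n_viruses = 15,
                             virus_len_range = c(5000L, 30000L),
                             cas_fraction = 0.5,
                             cas_distance_range = c(100L, 900L),
                             n_orphan_cas = 5,
                             orfs_per_kb = 0.3,
                             orf_len_range = c(300L, 900L),
                             hc_orf_fraction = 0.6,
                             taxonomy_depth = 7L,
                             mobility_fractions = c(conjugative = 0.4,
                                                    mobilizable = 0.3,
                                                    non_mobilizable = 0.3),
                             rng_seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] > 0
  for (f in c("plasmid_len_range", "chrom_len_range", "repeat_len_range",
              "spacer_len_range", "n_repeats_range", "virus_len_range",
              "orf_len_range", "cas_distance_range")) {
    if (!rng_ok(cfg[[f]])) stop_validation(sprintf("%s must be a non-empty range", f))
  }
  for (f in c("repeat_mut_rate", "protospacer_plasmid_fraction",
              "cas_fraction", "hc_orf_fraction")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop_validation(sprintf("%s must lie in [0, 1]", f))
  }
  if (abs(sum(cfg$mobility_fractions) - 1) > 1e-9)
    stop_validation("mobility_fractions must sum to 1")
  if (is.null(names(cfg$mobility_fractions)) ||
      !setequal(names(cfg$mobility_fractions),
                c("conjugative", "mobilizable", "non_mobilizable")))
    stop_validation("mobility_fractions must be named conjugative/mobilizable/non_mobilizable")
  if (cfg$taxonomy_depth != 7L)
    stop_validation("taxonomy_depth must be 7 (domain..species)")
  max_array <- cfg$n_repeats_range[2] * cfg$repeat_len_range[2] +
    (cfg$n_repeats_range[2] - 1) * cfg$spacer_len_range[2]
  if (cfg$plasmid_len_range[1] < max_array + 500)
    stop_validation(sprintf(
      "plasmid_len_range[1] = %d cannot host the largest configured array (%d bp) plus flanks",
      cfg$plasmid_len_range[1], max_array))
  invisible(TRUE)
}

# Rejection-sample a non-overlapping interval of length `len` on a
# replicon of length `total`, given occupied intervals (data.frame
# start/end) and a guard margin. Returns c(start, end) or NULL.
place_interval <- function(len, total, occupied, margin = 150L, tries = 300L) {
  if (total < len + 2L) return(NULL)
  for (i in seq_len(tries)) {
    s <- sample.int(total - len + 1L, 1L)
    e <- s + len - 1L
    if (nrow(occupied) == 0 ||
        all(interval_gap(occupied$start, occupied$end, s, e) > margin))
      return(c(s, e))
  }
  NULL
}

splice_into <- function(seq, sub, start) {
  n <- nchar(seq)
  paste0(substr(seq, 1, start - 1), sub, substr(seq, start + nchar(sub), n))
}

#' Plant a false-positive decoy repeat region into a sequence
#'
#' `iteron` decoys are 4-6 near-identical ~20 bp units separated by
#' near-identical equal-length linkers: they pass the repeat-conservation
#' and length-SEM filters but violate spacer conservation < 50%.
#' `transposon_tandem` decoys are conserved tandem units separated by
#' random linkers of strongly variable length: they violate the spacer
#' length SEM < 3 filter while keeping spacer conservation low. The decoy
#' is verified against the curation metrics and redrawn until it fails
#' exactly the tagged filter.
#'
#' Uses the current RNG stream.
#'
#' @param sequence host nucleotide string
#' @param kind `"iteron"` or `"transposon_tandem"`
#' @param at 1-based position at which to splice the decoy; random if NULL
#' @return list with `sequence` (modified) and `record` (data.frame:
#'   start, end, kind, violated_filter, n_units)
#' @export
plant_decoy <- function(sequence, kind = c("iteron", "transposon_tandem"),
                        at = NULL) {
  kind <- match.arg(kind)
  for (try in 1:50) {
    n_units <- sample(4:6, 1)
    if (kind == "iteron") {
      unit_len <- sample(18:24, 1)
      linker_len <- sample(16:30, 1)
      unit <- random_dna(unit_len)
      linker <- random_dna(linker_len)
      units <- vapply(seq_len(n_units), function(i) mutate_rate(unit, 0.01), "")
      linkers <- vapply(seq_len(n_units - 1), function(i) mutate_rate(linker, 0.01), "")
      tag <- "spacer_conservation"
      ok <- repeat_conservation(units) > 70 &&
        spacer_conservation(linkers) >= 50 &&
        spacer_length_sem(linkers) < 3
    } else {
      unit_len <- sample(25:40, 1)
      unit <- random_dna(unit_len)
      units <- vapply(seq_len(n_units), function(i) mutate_rate(unit, 0.01), "")
      linker_lens <- sample(15:80, n_units - 1, replace = TRUE)
      linkers <- vapply(linker_lens, random_dna, "")
      tag <- "spacer_length_sem"
      ok <- repeat_conservation(units) > 70 &&
        spacer_conservation(linkers) < 50 &&
        spacer_length_sem(linkers) >= 3
    }
    if (ok) break
  }
  if (!ok) stop("failed to construct a decoy violating only its tagged filter")
  body <- paste0(paste0(units[-n_units], linkers, collapse = ""), units[n_units])
  if (nchar(sequence) < nchar(body) + 2)
    stop_validation("sequence too short to host the decoy")
  if (is.null(at)) at <- sample.int(nchar(sequence) - nchar(body) + 1L, 1L)
  list(sequence = splice_into(sequence, body, at),
       record = data.frame(start = at, end = at + nchar(body) - 1L,
                           kind = kind, violated_filter = tag,
                           n_units = n_units))
}

# Build one true array guaranteed (by redraw) to pass all four curation
# filters. Spacers are sliced from a pre-generated random pool (drawn
# without replacement, so inter-spacer identity stays low) with lengths
# jittered around a per-array centre, mirroring the narrow within-array
# spacer-length distributions of real CRISPR arrays.
make_true_array <- function(cfg, pool, pool_used) {
  lo <- cfg$spacer_len_range[1]; hi <- cfg$spacer_len_range[2]
  for (try in 1:50) {
    n_rep <- sample(seq(cfg$n_repeats_range[1], cfg$n_repeats_range[2]), 1)
    rep_len <- sample(seq(cfg$repeat_len_range[1], cfg$repeat_len_range[2]), 1)
    master <- random_dna(rep_len)
    repeats <- vapply(seq_len(n_rep), function(i) mutate_rate(master, cfg$repeat_mut_rate), "")
    free <- which(!pool_used)
    if (length(free) < n_rep - 1) stop("spacer pool exhausted")
    idx <- sample(free, n_rep - 1)
    centre <- sample(seq(min(lo + 2L, hi), max(lo, hi - 2L)), 1)
    lens <- pmin(hi, pmax(lo, centre + sample(-2:2, n_rep - 1, replace = TRUE)))
    spacers <- substr(pool[idx], 1, lens)
    ok <- repeat_conservation(repeats) > 70 &&
      (length(spacers) < 2 || spacer_conservation(spacers) < 50) &&
      (length(spacers) < 2 || spacer_length_sem(spacers) < 3)
    if (ok) break
  }
  if (!ok) stop("failed to construct a filter-passing true array")
  list(master = master, repeats = repeats, spacers = spacers, used = idx)
}

cas_gene_sets <- list(
  "I-E"   = c("cas3", "cas8e", "cas11", "cas7", "cas5", "cas6e"),
  "I-F"   = c("cas3", "cas8f", "cas5f", "cas7f", "cas6f"),
  "I-B"   = c("cas3", "cas8b", "cas7", "cas5", "cas6"),
  "IV-A3" = c("csf1", "csf2", "csf3", "csf5"),
  "V-A"   = c("cas12a"))

#' Generate a synthetic plasmid community with planted ground truth
#'
#' Deterministic given `cfg$rng_seed`. Every planted true array passes,
#' by construction, the four curation filters (repeat conservation > 70%,
#' spacer conservation < 50%, spacer-length SEM < 3, no overlap with a
#' high-confidence ORF); every decoy violates exactly the filter named in
#' its `violated_filter` tag; every planted protospacer differs from its
#' source spacer by exactly the configured substitution count.
#'
#' @param cfg a [synthetic_config()]
#' @return object of class `plasmid_community`: `sequences`
#'   (DNAStringSet of replicons), `viruses` (DNAStringSet), `orfs`,
#'   `cas_operons`, `metadata`, `trusted_repeats` (data.frames) and
#'   `truth` (planted arrays/decoys/protospacers/operons)
#' @export
generate_community <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_synthetic_config(cfg)
  set.seed(cfg$rng_seed)

  ## --- replicons and metadata -------------------------------------------
  n_rep <- cfg$n_plasmids + cfg$n_chromosomes
  ids <- c(sprintf("plasmid_%03d", seq_len(cfg$n_plasmids)),
           sprintf("chrom_%03d", seq_len(cfg$n_chromosomes)))
  kind <- rep(c("plasmid", "chromosome"), c(cfg$n_plasmids, cfg$n_chromosomes))
  lens <- integer(n_rep)
  lens[kind == "plasmid"] <- sample(seq(cfg$plasmid_len_range[1], cfg$plasmid_len_range[2]),
                                    cfg$n_plasmids, replace = TRUE)
  lens[kind == "chromosome"] <- sample(seq(cfg$chrom_len_range[1], cfg$chrom_len_range[2]),
                                       cfg$n_chromosomes, replace = TRUE)

  # Balanced binary taxonomy: 2 labels per rank split, 64 species leaves.
  n_species <- 2^6
  species_idx <- sample.int(n_species, n_rep, replace = TRUE)
  tax <- sapply(seq_len(6), function(level) {
    sprintf("%s_%02d", TAX_RANKS[level + 1], (species_idx - 1) %/% 2^(6 - level) + 1)
  })
  taxonomy <- data.frame(domain = "d_Bacteria", tax)
  names(taxonomy) <- TAX_RANKS
  mobility <- rep(NA_character_, n_rep)
  mobility[kind == "plasmid"] <- sample(names(cfg$mobility_fractions),
                                        cfg$n_plasmids, replace = TRUE,
                                        prob = cfg$mobility_fractions)
  metadata <- data.frame(replicon_id = ids, kind = kind, taxonomy,
                         mobility = mobility, length_bp = lens)

  seqs <- setNames(vapply(lens, random_dna, ""), ids)
  occupied <- lapply(setNames(seq_len(n_rep), ids), function(i)
    data.frame(start = integer(), end = integer()))

  ## --- true arrays -------------------------------------------------------
  pool_size <- max(200L, 3L * cfg$n_true_arrays * cfg$n_repeats_range[2])
  pool <- vapply(rep(cfg$spacer_len_range[2], pool_size), random_dna, "")
  pool_used <- rep(FALSE, pool_size)

  arrays <- list()
  if (cfg$n_true_arrays > 0) {
    host_prob <- lens / sum(lens)
    for (a in seq_len(cfg$n_true_arrays)) {
      planted <- FALSE
      for (attempt in 1:50) {
        arr <- make_true_array(cfg, pool, pool_used)
        body <- paste0(paste0(arr$repeats[-length(arr$repeats)], arr$spacers,
                              collapse = ""), arr$repeats[length(arr$repeats)])
        ri <- sample.int(n_rep, 1, prob = host_prob)
        pos <- place_interval(nchar(body), lens[ri], occupied[[ri]])
        if (!is.null(pos)) {
          pool_used[arr$used] <- TRUE
          seqs[ri] <- splice_into(seqs[ri], body, pos[1])
          occupied[[ri]] <- rbind(occupied[[ri]],
                                  data.frame(start = pos[1], end = pos[2]))
          rc <- repeat_conservation(arr$repeats)
          sc <- if (length(arr$spacers) >= 2) spacer_conservation(arr$spacers) else NA
          sem <- if (length(arr$spacers) >= 2) spacer_length_sem(arr$spacers) else NA
          level <- if (length(arr$spacers) >= 4 && rc > 90 &&
                       !is.na(sc) && sc < 20 && !is.na(sem) && sem < 3) 4L else 3L
          arrays[[a]] <- list(array_id = sprintf("array_%03d", a),
                              replicon_id = ids[ri], start = pos[1], end = pos[2],
                              consensus = arr$master, repeats = arr$repeats,
                              spacers = arr$spacers,
                              evidence_class = level, has_cas = FALSE,
                              subtype = NA_character_)
          planted <- TRUE
        }
        if (planted) break
      }
      if (!planted) stop_validation(
        "replicon lengths cannot host the configured number of arrays (n_true_arrays)")
    }
  }

  ## --- decoys ------------------------------------------------------------
  decoys <- data.frame()
  if (cfg$n_decoys > 0) {
    host_prob <- lens / sum(lens)
    for (d in seq_len(cfg$n_decoys)) {
      placed <- FALSE
      for (attempt in 1:50) {
        kind_d <- if (d %% 2 == 1) "iteron" else "transposon_tandem"
        ri <- sample.int(n_rep, 1, prob = host_prob)
        # decoy body length is bounded by 6 units * 40 + 5 linkers * 80
        pos <- place_interval(650L, lens[ri], occupied[[ri]])
        if (is.null(pos)) next
        res <- plant_decoy(seqs[ri], kind_d, at = pos[1])
        seqs[ri] <- res$sequence
        rec <- res$record
        rec$decoy_id <- sprintf("decoy_%03d", d)
        rec$replicon_id <- ids[ri]
        occupied[[ri]] <- rbind(occupied[[ri]],
                                data.frame(start = rec$start, end = rec$end))
        decoys <- rbind(decoys, rec)
        placed <- TRUE
        break
      }
      if (!placed) stop_validation(
        "replicon lengths cannot host the configured number of decoys (n_decoys)")
    }
  }

  ## --- cas operons -------------------------------------------------------
  operons <- data.frame()
  op_n <- 0L
  add_operon <- function(ri, pos, subtype, linked_array) {
    op_n <<- op_n + 1L
    genes <- cas_gene_sets[[subtype]]
    has_ad <- runif(1) < 0.5
    if (has_ad) genes <- c("cas1", "cas2", genes)
    data.frame(operon_id = sprintf("cas_%03d", op_n),
               replicon_id = ids[ri], start = pos[1], end = pos[2],
               subtype = subtype, genes = paste(genes, collapse = ","),
               has_adaptation = has_ad,
               linked_array = linked_array)
  }
  if (length(arrays) > 0 && cfg$cas_fraction > 0) {
    n_with <- round(cfg$cas_fraction * length(arrays))
    with_cas <- sample(seq_along(arrays), n_with)
    for (a in with_cas) {
      arr <- arrays[[a]]
      ri <- match(arr$replicon_id, ids)
      op_len <- sample(2000:6000, 1)
      gap <- sample(seq(cfg$cas_distance_range[1], cfg$cas_distance_range[2]), 1)
      placed <- FALSE
      for (side in sample(c("right", "left"))) {
        s <- if (side == "right") arr$end + gap + 1L else arr$start - gap - op_len
        e <- s + op_len - 1L
        if (s < 1 || e > lens[ri]) next
        occ <- occupied[[ri]]
        if (any(pmax(occ$start, s) <= pmin(occ$end, e))) next
        subtype <- sample(names(cas_gene_sets), 1)
        operons <- rbind(operons, add_operon(ri, c(s, e), subtype, arr$array_id))
        occupied[[ri]] <- rbind(occ, data.frame(start = s, end = e))
        arrays[[a]]$has_cas <- TRUE
        arrays[[a]]$subtype <- subtype
        placed <- TRUE
        break
      }
    }
  }
  if (cfg$n_orphan_cas > 0) {
    host_prob <- lens / sum(lens)
    for (k in seq_len(cfg$n_orphan_cas)) {
      for (attempt in 1:50) {
        ri <- sample.int(n_rep, 1, prob = host_prob)
        op_len <- sample(2000:6000, 1)
        pos <- place_interval(op_len, lens[ri], occupied[[ri]], margin = 11000L)
        if (is.null(pos)) next
        subtype <- sample(names(cas_gene_sets), 1)
        operons <- rbind(operons, add_operon(ri, pos, subtype, NA_character_))
        occupied[[ri]] <- rbind(occupied[[ri]],
                                data.frame(start = pos[1], end = pos[2]))
        break
      }
    }
  }

  ## --- ORFs --------------------------------------------------------------
  orfs <- data.frame()
  orf_n <- 0L
  for (ri in seq_len(n_rep)) {
    n_orf <- round(lens[ri] / 1000 * cfg$orfs_per_kb)
    for (k in seq_len(n_orf)) {
      ol <- sample(seq(cfg$orf_len_range[1], cfg$orf_len_range[2]), 1)
      pos <- place_interval(ol, lens[ri], occupied[[ri]], margin = 20L, tries = 60L)
      if (is.null(pos)) next
      orf_n <- orf_n + 1L
      conf <- if (runif(1) < cfg$hc_orf_fraction)
        round(runif(1, 90, 100), 1) else round(runif(1, 0, 89.9), 1)
      orfs <- rbind(orfs, data.frame(
        orf_id = sprintf("orf_%04d", orf_n), replicon_id = ids[ri],
        start = pos[1], end = pos[2],
        strand = sample(c("+", "-"), 1), confidence = conf))
      occupied[[ri]] <- rbind(occupied[[ri]],
                              data.frame(start = pos[1], end = pos[2]))
    }
  }

  ## --- viruses -----------------------------------------------------------
  vlens <- sample(seq(cfg$virus_len_range[1], cfg$virus_len_range[2]),
                  cfg$n_viruses, replace = TRUE)
  viruses <- setNames(vapply(vlens, random_dna, ""),
                      sprintf("virus_%03d", seq_len(cfg$n_viruses)))

  ## --- protospacers ------------------------------------------------------
  # Sources are spacers of cas-linked arrays: these are guaranteed to
  # survive the typed-spacer inclusion rule downstream.
  proto <- data.frame()
  if (cfg$n_protospacers > 0) {
    src <- do.call(rbind, lapply(arrays, function(a) {
      if (!a$has_cas || length(a$spacers) == 0) return(NULL)
      data.frame(spacer_id = sprintf("%s_sp%02d", a$array_id, seq_along(a$spacers)),
                 sequence = a$spacers, source_replicon = a$replicon_id,
                 source_array = a$array_id)
    }))
    if (is.null(src) || nrow(src) == 0)
      stop_validation("no cas-linked arrays available to source protospacers from")
    hc <- orfs[orfs$confidence >= 90 &
                 metadata$kind[match(orfs$replicon_id, ids)] == "plasmid", ]
    v_occ <- lapply(setNames(seq_len(cfg$n_viruses), names(viruses)), function(i)
      data.frame(start = integer(), end = integer()))
    orf_used <- rep(FALSE, nrow(hc))
    for (p in seq_len(cfg$n_protospacers)) {
      class_p <- if (runif(1) < cfg$protospacer_plasmid_fraction) "plasmid" else "virus"
      planted <- FALSE
      for (attempt in 1:100) {
        si <- sample.int(nrow(src), 1)
        sp <- src[si, ]
        slen <- nchar(sp$sequence)
        body <- mutate_substitutions(sp$sequence, cfg$protospacer_mismatches)
        strand <- sample(c("+", "-"), 1)
        if (strand == "-") body <- revcomp(body)
        if (class_p == "plasmid") {
          cand <- which(!orf_used & hc$replicon_id != sp$source_replicon &
                          (hc$end - hc$start + 1) >= slen + 4)
          if (length(cand) == 0) next
          oi <- sample(cand, 1)
          s <- hc$start[oi] + sample.int(hc$end[oi] - hc$start[oi] + 1 - slen, 1)
          ri <- match(hc$replicon_id[oi], ids)
          seqs[ri] <- splice_into(seqs[ri], body, s)
          orf_used[oi] <- TRUE
          proto <- rbind(proto, data.frame(
            protospacer_id = sprintf("proto_%03d", p),
            spacer_id = sp$spacer_id, source_replicon = sp$source_replicon,
            target_id = hc$replicon_id[oi], target_class = "plasmid",
            start = s, end = s + slen - 1L, strand = strand,
            n_mismatches = cfg$protospacer_mismatches))
        } else {
          vi <- sample.int(cfg$n_viruses, 1)
          pos <- place_interval(slen, vlens[vi], v_occ[[vi]], margin = 30L)
          if (is.null(pos)) next
          viruses[vi] <- splice_into(viruses[vi], body, pos[1])
          v_occ[[vi]] <- rbind(v_occ[[vi]],
                               data.frame(start = pos[1], end = pos[2]))
          proto <- rbind(proto, data.frame(
            protospacer_id = sprintf("proto_%03d", p),
            spacer_id = sp$spacer_id, source_replicon = sp$source_replicon,
            target_id = names(viruses)[vi], target_class = "virus",
            start = pos[1], end = pos[2], strand = strand,
            n_mismatches = cfg$protospacer_mismatches))
        }
        planted <- TRUE
        break
      }
      if (!planted) stop_validation(
        "could not place the configured number of protospacers (n_protospacers)")
    }
  }

  ## --- trusted repeats ---------------------------------------------------
  trusted <- data.frame()
  if (length(arrays) > 0) {
    trusted <- data.frame(
      repeat_id = vapply(arrays, `[[`, "", "array_id"),
      seq = vapply(arrays, `[[`, "", "consensus"),
      subtype = vapply(arrays, `[[`, "", "subtype"))
    trusted$repeat_id <- paste0("trusted_", trusted$repeat_id)
  }
  # a few extra trusted repeats unrelated to the community
  extra_n <- 5L
  trusted <- rbind(trusted, data.frame(
    repeat_id = sprintf("trusted_extra_%02d", seq_len(extra_n)),
    seq = vapply(sample(seq(cfg$repeat_len_range[1], cfg$repeat_len_range[2]),
                        extra_n, replace = TRUE), random_dna, ""),
    subtype = sample(names(cas_gene_sets), extra_n, replace = TRUE)))

  arrays_table <- if (length(arrays) > 0) data.frame(
    array_id = vapply(arrays, `[[`, "", "array_id"),
    replicon_id = vapply(arrays, `[[`, "", "replicon_id"),
    start = vapply(arrays, `[[`, 0L, "start"),
    end = vapply(arrays, `[[`, 0L, "end"),
    n_repeats = vapply(arrays, function(a) length(a$repeats), 0L),
    consensus = vapply(arrays, `[[`, "", "consensus"),
    evidence_class = vapply(arrays, `[[`, 0L, "evidence_class"),
    has_cas = vapply(arrays, `[[`, FALSE, "has_cas"),
    subtype = vapply(arrays, `[[`, "", "subtype")
  ) else data.frame()

  structure(list(
    config = cfg,
    sequences = Biostrings::DNAStringSet(seqs),
    viruses = Biostrings::DNAStringSet(viruses),
    orfs = orfs,
    cas_operons = operons,
    metadata = metadata,
    trusted_repeats = trusted,
    truth = list(arrays = arrays, arrays_table = arrays_table,
                 decoys = decoys, protospacers = proto,
                 cas_operons = operons)
  ), class = "plasmid_community")
}

#' @export
print.plasmid_community <- function(x, ...) {
  cat(sprintf("plasmid_community: %d replicons (%d plasmids), %d viruses\n",
              length(x$sequences), sum(x$metadata$kind == "plasmid"),
              length(x$viruses)))
  cat(sprintf("  planted: %d arrays, %d decoys, %d cas operons, %d protospacers\n",
              length(x$truth$arrays), nrow(x$truth$decoys),
              nrow(x$cas_operons), nrow(x$truth$protospacers)))
  invisible(x)
}

#' Write a synthetic community to standard-format files
#'
#' Emits replicon and virus FASTA, a GFF3 with CDS (attribute
#' `confidence`) and cas_operon features (attributes `subtype`,
#' `adaptation`, `genes`), the replicon metadata TSV, the trusted-repeat
#' FASTA, and plain-TSV ground-truth tables. All GFF coordinates are
#' 1-based inclusive.
#'
#' @param community a [generate_community()] result
#' @param dir output directory (created if missing)
#' @return invisibly, the named vector of written paths
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(replicons = file.path(dir, "replicons.fna"),
             viruses = file.path(dir, "viruses.fna"),
             features = file.path(dir, "features.gff3"),
             metadata = file.path(dir, "metadata.tsv"),
             trusted = file.path(dir, "trusted_repeats.fna"),
             truth_arrays = file.path(dir, "truth_arrays.tsv"),
             truth_decoys = file.path(dir, "truth_decoys.tsv"),
             truth_protospacers = file.path(dir, "truth_protospacers.tsv"))
  Biostrings::writeXStringSet(community$sequences, paths["replicons"])
  Biostrings::writeXStringSet(community$viruses, paths["viruses"])
  write_feature_gff(community$orfs, community$cas_operons, paths["features"])
  write_tsv(community$metadata, paths["metadata"])
  tr <- Biostrings::DNAStringSet(setNames(community$trusted_repeats$seq,
                                          ifelse(is.na(community$trusted_repeats$subtype),
                                                 community$trusted_repeats$repeat_id,
                                                 paste0(community$trusted_repeats$repeat_id,
                                                        " subtype=", community$trusted_repeats$subtype))))
  Biostrings::writeXStringSet(tr, paths["trusted"])
  write_tsv(community$truth$arrays_table, paths["truth_arrays"])
  write_tsv(community$truth$decoys, paths["truth_decoys"])
  write_tsv(community$truth$protospacers, paths["truth_protospacers"])
  invisible(paths)
}
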