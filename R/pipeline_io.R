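# Readers/writers for the standard formats, pipeline configuration and
# the end-to-end orchestrator. All emitted/ingested GFF3 coordinates are
# 1-based inclusive; tables have fixed headers that are schema-checked
# on read-back.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a TSV with schema checking
#'
#' @param path file path
#' @param required_cols column names that must be present
#' @return data.frame
#' @export
read_tsv_checked <- function(path, required_cols = character()) {
  if (!file.exists(path)) stop_parse(paste0("no such file: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0)
    stop_validation(sprintf("%s: missing required column(s): %s",
                            path, paste(missing, collapse = ", ")))
  df
}

#' Read replicon metadata (TSV)
#'
#' Expects the fixed header replicon_id, kind, domain..species,
#' mobility, length_bp.
#' @param path TSV path
#' @return data.frame
#' @export
read_replicon_metadata <- function(path) {
  read_tsv_checked(path, c("replicon_id", "kind", TAX_RANKS,
                           "mobility", "length_bp"))
}

#' Read a FASTA of replicons with position-aware validation
#'
#' Sequences must contain only A, C, G, T or N; the first offending
#' character is reported with its file line and column.
#'
#' @param path FASTA path
#' @return named DNAStringSet
#' @export
read_replicon_fasta <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("no such file: ", path))
  lines <- readLines(path)
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (startsWith(l, ">") || nchar(l) == 0) next
    bad <- regexpr("[^ACGTNacgtn]", l)
    if (bad > 0)
      stop_parse(sprintf("%s: illegal sequence character '%s' at line %d, column %d",
                         path, substr(l, bad, bad), ln, bad))
  }
  Biostrings::readDNAStringSet(path)
}

#' Write ORF and cas-operon annotations as GFF3
#'
#' CDS features carry a `confidence` attribute in `[0, 100]`; cas_operon
#' features carry `subtype`, `adaptation` and `genes` attributes.
#'
#' @param orfs ORF data.frame (orf_id, replicon_id, start, end, strand,
#'   confidence)
#' @param operons cas-operon data.frame (operon_id, replicon_id, start,
#'   end, subtype, genes, has_adaptation)
#' @param path output GFF3 path
#' @export
write_feature_gff <- function(orfs, operons, path) {
  grs <- list()
  if (!is.null(orfs) && nrow(orfs) > 0) {
    g <- GenomicRanges::GRanges(orfs$replicon_id,
                                IRanges::IRanges(orfs$start, orfs$end),
                                strand = orfs$strand)
    S4Vectors::mcols(g)$type <- "CDS"
    S4Vectors::mcols(g)$phase <- 0L
    S4Vectors::mcols(g)$ID <- orfs$orf_id
    S4Vectors::mcols(g)$confidence <- orfs$confidence
    grs$orfs <- g
  }
  if (!is.null(operons) && nrow(operons) > 0) {
    g <- GenomicRanges::GRanges(operons$replicon_id,
                                IRanges::IRanges(operons$start, operons$end),
                                strand = "+")
    S4Vectors::mcols(g)$type <- "cas_operon"
    S4Vectors::mcols(g)$ID <- operons$operon_id
    S4Vectors::mcols(g)$subtype <- operons$subtype
    S4Vectors::mcols(g)$adaptation <- tolower(as.character(operons$has_adaptation))
    S4Vectors::mcols(g)$genes <- operons$genes
    grs$operons <- g
  }
  if (length(grs) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  all <- suppressWarnings(do.call(c, unname(grs)))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read ORF and cas-operon annotations from GFF3
#'
#' @param path GFF3 path written by [write_feature_gff()] or compatible
#' @return list with `orfs` and `cas_operons` data.frames
#' @export
read_feature_gff <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("no such file: ", path))
  g <- tryCatch(rtracklayer::import(path, format = "gff3"),
                error = function(e) stop_parse(paste0(path, ": ", conditionMessage(e))))
  m <- S4Vectors::mcols(g)
  type <- as.character(m$type)
  orfs <- data.frame(orf_id = character(), replicon_id = character(),
                     start = integer(), end = integer(),
                     strand = character(), confidence = numeric())
  ops <- data.frame(operon_id = character(), replicon_id = character(),
                    start = integer(), end = integer(), subtype = character(),
                    genes = character(), has_adaptation = logical())
  is_cds <- type == "CDS"
  if (any(is_cds)) {
    orfs <- data.frame(
      orf_id = as.character(m$ID[is_cds]),
      replicon_id = as.character(GenomicRanges::seqnames(g)[is_cds]),
      start = BiocGenerics::start(g)[is_cds],
      end = BiocGenerics::end(g)[is_cds],
      strand = as.character(BiocGenerics::strand(g)[is_cds]),
      confidence = as.numeric(m$confidence[is_cds]))
  }
  is_op <- type == "cas_operon"
  if (any(is_op)) {
    ops <- data.frame(
      operon_id = as.character(m$ID[is_op]),
      replicon_id = as.character(GenomicRanges::seqnames(g)[is_op]),
      start = BiocGenerics::start(g)[is_op],
      end = BiocGenerics::end(g)[is_op],
      subtype = as.character(m$subtype[is_op]),
      genes = as.character(m$genes[is_op]),
      has_adaptation = tolower(as.character(m$adaptation[is_op])) == "true")
  }
  list(orfs = orfs, cas_operons = ops)
}

#' Write curated arrays as GFF3 (repeat_region with children)
#'
#' @param arrays list of arrays
#' @param path output path
#' @export
write_arrays_gff <- function(arrays, path) {
  if (length(arrays) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- list()
  for (a in arrays) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = a$replicon_id, type = "repeat_region",
      start = a$start, end = a$end,
      ID = a$array_id, Parent = NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = a$replicon_id, type = "direct_repeat",
      start = a$repeats$start, end = a$repeats$end,
      ID = sprintf("%s_r%02d", a$array_id, seq_len(nrow(a$repeats))),
      Parent = a$array_id)
    if (nrow(a$spacers) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = a$replicon_id, type = "spacer",
        start = a$spacers$start, end = a$spacers$end,
        ID = sprintf("%s_s%02d", a$array_id, seq_len(nrow(a$spacers))),
        Parent = a$array_id)
  }
  df <- do.call(rbind, rows)
  g <- GenomicRanges::GRanges(df$seqid, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(g)$type <- df$type
  S4Vectors::mcols(g)$ID <- df$ID
  S4Vectors::mcols(g)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage parameter with its default: quarantine thresholds
#' 70/50/3 and ORF confidence 90, 1 kb cas rescue, 95/95 trusted-repeat
#' match, 100 bp secondary clustering, minimum 3 repeats, 10 kb linkage,
#' 85% repeat association, e-value cutoff 0.05, and permutation counts
#' 9999 (IndVal) / 100 (confinement). Round-trips losslessly through
#' YAML via [write_config()]/[read_config()].
#'
#' @param out_dir output directory
#' @param seed master seed for every stochastic stage
#' @param synth a [synthetic_config()] (its `rng_seed` is overridden by
#'   `seed`), or NULL to read inputs from `input_dir`
#' @param input_dir directory with replicons.fna, features.gff3,
#'   metadata.tsv, trusted_repeats.fna, viruses.fna
#' @param repeat_conservation_min,spacer_conservation_max,spacer_sem_max,orf_conf_min quarantine thresholds
#' @param rescue_cas_dist,trusted_identity,trusted_coverage rescue rule parameters
#' @param secondary_cluster_gap,min_repeats secondary-search clustering gap and repeat minimum
#' @param link_dist,assoc_identity locus assembly parameters
#' @param e_cutoff spacer match expectation cutoff
#' @param indval_mode,n_perm_indval,n_perm_confinement statistics parameters
#' @param alpha significance level
#' @param log_level "quiet" or "info"
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir = tempfile("crisprmob_"),
                            seed = 1L,
                            synth = synthetic_config(),
                            input_dir = NULL,
                            repeat_conservation_min = 70,
                            spacer_conservation_max = 50,
                            spacer_sem_max = 3,
                            orf_conf_min = 90,
                            rescue_cas_dist = 1000,
                            trusted_identity = 95,
                            trusted_coverage = 95,
                            secondary_cluster_gap = 100,
                            min_repeats = 3,
                            link_dist = 10000,
                            assoc_identity = 85,
                            e_cutoff = 0.05,
                            indval_mode = "group_equalized",
                            n_perm_indval = 9999,
                            n_perm_confinement = 100,
                            alpha = 0.05,
                            log_level = "info") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize a pipeline configuration to YAML
#' @param config a [pipeline_config()]
#' @param path output path
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$synth)) {
    x$synth <- unclass(x$synth)
    # named vectors must serialise as YAML maps, not bare sequences
    x$synth$mobility_fractions <- as.list(x$synth$mobility_fractions)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path
#' @return `pipeline_config`
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$synth)) {
    s <- x$synth
    s$mobility_fractions <- unlist(s$mobility_fractions)
    x$synth <- do.call(synthetic_config, s[names(s) %in% names(formals(synthetic_config))])
  }
  cfg <- do.call(pipeline_config, x[names(x) %in% names(formals(pipeline_config))])
  cfg
}

plog <- function(config, fmt, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf(paste0("[crisprmob] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes synth (or input loading), detection, curation, secondary
#' search, locus assembly, prevalence/IndVal/Fisher statistics, spacer
#' matching, conjugative weighting, and the targeting network with its
#' confinement permutation null, persisting all stage outputs and a run
#' manifest under `config$out_dir`. Reruns with identical configuration
#' reproduce identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return result bundle (named list of all stage objects), invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ## stage: inputs ---------------------------------------------------------
  if (!is.null(config$synth)) {
    sc <- config$synth
    sc$rng_seed <- config$seed
    community <- generate_community(sc)
    plog(config, "synth: %d replicons, %d planted arrays, %d decoys",
         length(community$sequences), length(community$truth$arrays),
         nrow(community$truth$decoys))
  } else {
    if (is.null(config$input_dir))
      stop_validation("either synth or input_dir must be given")
    community <- list(
      sequences = read_replicon_fasta(file.path(config$input_dir, "replicons.fna")),
      viruses = read_replicon_fasta(file.path(config$input_dir, "viruses.fna")),
      metadata = read_replicon_metadata(file.path(config$input_dir, "metadata.tsv")),
      trusted_repeats = read_trusted_repeats(file.path(config$input_dir, "trusted_repeats.fna")),
      truth = NULL)
    feats <- read_feature_gff(file.path(config$input_dir, "features.gff3"))
    community$orfs <- feats$orfs
    community$cas_operons <- feats$cas_operons
  }

  ## stage: detect ---------------------------------------------------------
  candidates <- detect_arrays(community$sequences)
  plog(config, "detect: %d candidate arrays", length(candidates))

  ## stage: curate ---------------------------------------------------------
  curated <- curate_arrays(candidates, community$orfs, community$cas_operons,
                           community$trusted_repeats,
                           min_orf_conf = config$orf_conf_min)
  retained <- Filter(function(a) isTRUE(a$retained), curated)
  retained3 <- min_repeat_filter(retained)
  plog(config, "curate: %d retained (%d with >= %d repeats)",
       length(retained), length(retained3), config$min_repeats)

  # mask everything detected (all candidates, all repeat counts)
  masked <- mask_arrays(community$sequences, curated)
  secondary <- secondary_repeat_search(community$trusted_repeats, masked,
                                       cluster_gap = config$secondary_cluster_gap)
  plog(config, "secondary search: %d additional arrays", length(secondary))
  analysis_arrays <- c(retained3, secondary)
  mask_all <- c(curated, secondary)
  masked <- mask_arrays(community$sequences, mask_all)

  ## stage: assemble -------------------------------------------------------
  loci <- link_arrays_to_operons(analysis_arrays, community$cas_operons,
                                 max_dist = config$link_dist)
  loci <- associate_distant_arrays(loci = loci, min_identity = config$assoc_identity)
  summary <- summarize_loci(loci)
  plog(config, "assemble: %d loci (%d complete)", nrow(summary$loci),
       sum(summary$loci$completeness == "complete"))

  ## stage: stats ----------------------------------------------------------
  prev <- prevalence(summary, community$metadata)
  pm <- presence_matrix(summary, community$metadata)
  iv <- if (sum(pm$matrix) > 0)
    indval(pm$matrix, pm$groups, mode = config$indval_mode,
           n_perm = config$n_perm_indval, seed = config$seed,
           alpha = config$alpha)
  else NULL
  # conjugative transfer vs CRISPR-Cas carriage (plasmids only)
  md_p <- community$metadata[community$metadata$kind == "plasmid", ]
  carriers <- unique(summary$loci$replicon_id)
  has_sys <- md_p$replicon_id %in% carriers
  is_conj <- md_p$mobility == "conjugative"
  fisher_tab <- matrix(c(sum(has_sys & is_conj), sum(has_sys & !is_conj),
                         sum(!has_sys & is_conj), sum(!has_sys & !is_conj)),
                       2, byrow = TRUE,
                       dimnames = list(c("crispr", "no_crispr"),
                                       c("conjugative", "non_conjugative")))
  enr <- enrichment_2x2(fisher_tab)

  ## stage: target ---------------------------------------------------------
  spacers <- collect_spacers(loci, community$metadata,
                             repeat_type_lookup = community$trusted_repeats,
                             min_identity = config$assoc_identity)
  pdb <- build_orf_db(masked[community$metadata$replicon_id[
    community$metadata$kind == "plasmid"]],
    community$orfs, min_conf = config$orf_conf_min)
  vdb <- build_virus_db(community$viruses)
  matches <- match_spacers(spacers, pdb, vdb, e_cutoff = config$e_cutoff)
  props <- target_class_proportions(matches, spacers)
  mob <- setNames(community$metadata$mobility, community$metadata$replicon_id)
  weights <- conjugative_weighting(matches, mob)
  plog(config, "target: %d spacers, %d matches", nrow(spacers), nrow(matches))

  ## stage: network --------------------------------------------------------
  pairs <- build_pairs(matches, spacers)
  conf <- if (nrow(pairs) > 0)
    permuted_confinement(pairs, community$metadata,
                         n_perm = config$n_perm_confinement,
                         seed = config$seed)
  else NULL
  net <- export_network(pairs, community$metadata,
                        graphml_path = file.path(config$out_dir, "network.graphml"),
                        tsv_path = file.path(config$out_dir, "network_edges.tsv"),
                        crispr_replicons = carriers)

  ## stage: persist --------------------------------------------------------
  write_tsv(arrays_table(curated), file.path(config$out_dir, "arrays_curated.tsv"))
  write_arrays_gff(analysis_arrays, file.path(config$out_dir, "arrays.gff3"))
  Biostrings::writeXStringSet(masked, file.path(config$out_dir, "masked.fna"))
  write_tsv(summary$loci, file.path(config$out_dir, "loci.tsv"))
  write_tsv(prev, file.path(config$out_dir, "prevalence.tsv"))
  if (!is.null(iv)) write_tsv(iv, file.path(config$out_dir, "indval.tsv"))
  write_tsv(spacers, file.path(config$out_dir, "spacers.tsv"))
  write_tsv(matches, file.path(config$out_dir, "matches.tsv"))
  if (!is.null(conf)) write_tsv(conf, file.path(config$out_dir, "confinement.tsv"))

  cfg_file <- file.path(config$out_dir, "config.yaml")
  write_config(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("crisprmob")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    counts = list(replicons = length(community$sequences),
                  candidates = length(candidates),
                  retained = length(retained),
                  analysis_arrays = length(analysis_arrays),
                  loci = nrow(summary$loci),
                  complete = sum(summary$loci$completeness == "complete"),
                  orphan_array = sum(summary$loci$completeness == "orphan_array"),
                  orphan_cas = sum(summary$loci$completeness == "orphan_cas"),
                  spacers = nrow(spacers),
                  matches = nrow(matches),
                  pairs = nrow(pairs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(community = community, candidates = candidates,
                 curated = curated, analysis_arrays = analysis_arrays,
                 masked = masked, loci = loci, summary = summary,
                 prevalence = prev, indval = iv, fisher = enr,
                 fisher_table = fisher_tab, spacers = spacers,
                 matches = matches, proportions = props, weights = weights,
                 pairs = pairs, confinement = conf, network = net,
                 manifest = manifest))
}

#' Read a trusted-repeat FASTA
#'
#' Headers may carry `subtype=<label>`; entries without it are untyped.
#' @param path FASTA path
#' @return data.frame with repeat_id, seq, subtype
#' @export
read_trusted_repeats <- function(path) {
  x <- read_replicon_fasta(path)
  nm <- names(x)
  subtype <- ifelse(grepl("subtype=", nm),
                    sub(".*subtype=([^ ]+).*", "\\1", nm), NA_character_)
  data.frame(repeat_id = sub(" .*", "", nm),
             seq = as.character(x), subtype = subtype)
}
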