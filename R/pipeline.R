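#' Pipeline configuration
#'
#' Collects every tunable of the mining pipeline with its default:
#' greedy identity tiers (0.9/0.5), tree dissection height
#' (`-ln(0.01)/2` ~ 2.30), consensus mask threshold (0.5), alignment
#' filter thresholds (gap fraction 0.5, homogeneity 0.1), neighborhood
#' window (10 genes each side), candidate neighbor rank (2), precursor
#' length cap (150) and majority (0.5), directon gap (100 bases),
#' association thresholds (more than 20 loci, weighted frequency at
#' least 1%), gap penalties (11/1), the cross-score significance gate,
#' residue sets, and the seed. The config is serialized verbatim into
#' every run manifest.
#'
#' @param ... overrides of the defaults listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tier1 = 0.9, tier2 = 0.5,
    depth_cutoff = -log(0.01) / 2,
    h_consensus = 0.5,
    filter_max_gap = 0.5, filter_min_homog = 0.1,
    window = 10L,
    candidate_rank = 2L, length_cap = 150L, majority = 0.5,
    directon_gap = 100L,
    assoc_min_loci = 20L, assoc_min_wfreq = 0.01,
    gap_open = 11, gap_extend = 1, score_floor = 1,
    evalue_max = 1e-6, ka_lambda = 0.267, ka_k = 0.041,
    hydrophobic = hydrophobic_set(), small_set = small_residue_set(),
    nterm = 30L,
    seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ",
                             paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

# cheap deterministic content hash (polynomial, 31-bit) for manifests
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x01"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full graspetide mining pipeline
#'
#' Composition of every stage: anchor neighborhoods and directons,
#' homolog clustering of all neighborhood proteins, the precursor
#' candidate filter, motif scans and known/new/candidate classification
#' per final cluster, and redundancy-weighted directon association
#' statistics with the reporting thresholds. The run is fully
#' deterministic for a given config.
#'
#' @param features a `gene_features` data.frame ([read_features()]).
#' @param proteins named character vector of protein sequences keyed by
#'   `protein_id`.
#' @param anchor_ids gene ids of the anchor (ATP-grasp) genes.
#' @param config a [pipeline_config()].
#' @param reference_seqs optional named character vector of reference
#'   precursors (known-precursor evidence).
#' @param motif_library list of [motif_pattern]s (default
#'   [graspetide_motifs()]).
#' @param annotations optional character vector of protein ids annotated
#'   as precursors by an external profile search.
#' @return a `mine_result` list: `loci` (per anchor: neighborhood with
#'   ranks and directons), `clustering` (from [cluster_homologs()]),
#'   `candidates`, `precursors` (per final cluster: status and
#'   evidence), `calls` (the full `precursor_call` objects),
#'   `associations` (all records) and `associations_kept`, plus
#'   `config` and a `manifest` with input hashes and per-stage counts.
#' @export
run_mine <- function(features, proteins, anchor_ids,
                     config = pipeline_config(),
                     reference_seqs = NULL,
                     motif_library = graspetide_motifs(),
                     annotations = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  features <- validate_features(as.data.frame(features))
  anchor_ids <- anchor_ids[anchor_ids %in% features$gene_id]
  if (length(anchor_ids) == 0L) stop("no anchor genes found")

  # 1. neighborhoods and directons
  loci <- lapply(anchor_ids, function(a) {
    loc <- extract_neighborhood(features, a, window = config$window)
    assemble_directons(loc, max_gap = config$directon_gap)
  })
  names(loci) <- anchor_ids

  # 2. homolog clustering of all neighborhood proteins
  ids <- unique(unlist(lapply(loci, function(l) l$protein_id)))
  miss <- setdiff(ids, names(proteins))
  if (length(miss) > 0L) stop("missing protein sequence(s): ",
                              paste(head(miss, 5), collapse = ", "))
  seqs <- proteins[ids]
  ch <- cluster_homologs(seqs, tier1 = config$tier1, tier2 = config$tier2,
                         depth_cutoff = config$depth_cutoff,
                         gap_open = config$gap_open,
                         gap_extend = config$gap_extend,
                         score_floor = config$score_floor,
                         evalue_max = config$evalue_max,
                         ka_lambda = config$ka_lambda, ka_k = config$ka_k)

  # 3. minimum |rank| of each protein relative to any anchor
  anchor_rank <- rep(Inf, length(ids))
  names(anchor_rank) <- ids
  for (l in loci) {
    r <- abs(l$rank)
    upd <- r < anchor_rank[l$protein_id]
    anchor_rank[l$protein_id[upd]] <- r[upd]
  }

  # 4. candidate filter over final clusters
  lens <- setNames(nchar(seqs), names(seqs))
  cand <- candidate_filter(ch$final, lens, anchor_rank,
                           max_len = config$length_cap,
                           max_rank = config$candidate_rank,
                           majority = config$majority)

  # families containing an anchor protein are enzyme families, not
  # precursor candidates
  anchor_prot <- vapply(loci, function(l) l$protein_id[l$rank == 0L], "")
  anchor_families <- unique(ch$final[anchor_prot])

  # 5. classification per final cluster
  calls <- list()
  prec_rows <- list()
  for (k in sort(unique(ch$final))) {
    mem <- names(ch$final)[ch$final == k]
    aln <- align_msa(seqs[mem], gap_open = config$gap_open,
                     gap_extend = config$gap_extend)
    prof <- derive_consensus(aln, h_consensus = config$h_consensus)
    passed <- cand$kept[cand$cluster == k]
    call <- classify_precursor(seqs[mem], prof, passed,
                               reference_seqs = reference_seqs,
                               motif_library = motif_library,
                               annotations = annotations,
                               nterm = config$nterm)
    is_anchor <- k %in% anchor_families
    calls[[as.character(k)]] <- call
    bonds <- call$bond_candidates
    prec_rows[[length(prec_rows) + 1L]] <- data.frame(
      cluster = k, n = length(mem), is_anchor_family = is_anchor,
      status = if (is_anchor) "anchor" else call$status,
      ref_overlap = call$evidence[["ref_overlap"]],
      motif_match = call$evidence[["motif_match"]],
      annotated = call$evidence[["annotated"]],
      passed_filter = call$evidence[["passed_filter"]],
      conserved_doublet = call$evidence[["conserved_doublet"]],
      gg_leader_nterm = call$evidence[["gg_leader_nterm"]],
      bond_positions = paste(sprintf("%d:%s", bonds$position, bonds$residue),
                             collapse = ","),
      thioether_positions = paste(call$thioether_candidates$position,
                                  collapse = ","),
      stringsAsFactors = FALSE)
  }
  precursors <- do.call(rbind, prec_rows)

  # 6. association statistics over anchor directons
  red_group <- ch$provenance$tier1[match(anchor_prot, ch$provenance$id)]
  weights <- locus_weights(anchor_ids, red_group)
  locus_families <- lapply(loci, function(l) {
    fams <- unique(ch$final[l$protein_id[l$in_anchor_directon]])
    setdiff(as.character(fams), as.character(anchor_families))
  })
  assoc <- weighted_association(locus_families, weights)
  assoc_kept <- filter_associations(assoc, min_loci = config$assoc_min_loci,
                                    min_wfreq = config$assoc_min_wfreq)

  manifest <- list(
    config = unclass(config),
    inputs = list(n_features = nrow(features), n_proteins = length(proteins),
                  n_anchors = length(anchor_ids),
                  features_hash = content_hash(apply(features, 1L, paste,
                                                     collapse = "\t")),
                  proteins_hash = content_hash(paste(names(proteins),
                                                     proteins))),
    counts = list(neighborhood_proteins = length(ids),
                  tier1_clusters = length(ch$tier1$representatives),
                  tier2_clusters = length(ch$tier2$representatives),
                  final_clusters = length(unique(ch$final)),
                  candidate_clusters = sum(cand$kept),
                  known = sum(precursors$status == "known"),
                  new = sum(precursors$status == "new"),
                  candidate = sum(precursors$status == "candidate"),
                  associations_kept = nrow(assoc_kept)))

  structure(list(loci = loci, clustering = ch, candidates = cand,
                 precursors = precursors, calls = calls,
                 associations = assoc, associations_kept = assoc_kept,
                 weights = weights, anchor_families = anchor_families,
                 config = config, manifest = manifest),
            class = "mine_result")
}

#' @export
print.mine_result <- function(x, ...) {
  cn <- x$manifest$counts
  cat("graspmine run:\n")
  cat(sprintf("  %d loci, %d neighborhood proteins\n",
              length(x$loci), cn$neighborhood_proteins))
  cat(sprintf("  clusters: %d tier-1 -> %d tier-2 -> %d final\n",
              cn$tier1_clusters, cn$tier2_clusters, cn$final_clusters))
  cat(sprintf("  precursors: %d known / %d new / %d candidate clusters\n",
              cn$known, cn$new, cn$candidate))
  cat(sprintf("  associations passing thresholds: %d\n",
              cn$associations_kept))
  invisible(x)
}

#' Write the report bundle of a mining run
#'
#' Emits deterministic, byte-stable TSV reports (loci, clusters,
#' precursors, associations), the UPGMA tree as newick, and the YAML run
#' manifest. Writing the same result twice produces identical bytes.
#'
#' @param results a `mine_result` from [run_mine()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_reports <- function(results, out_dir) {
  stopifnot(inherits(results, "mine_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(loci = file.path(out_dir, "loci.tsv"),
             clusters = file.path(out_dir, "clusters.tsv"),
             precursors = file.path(out_dir, "precursors.tsv"),
             associations = file.path(out_dir, "associations.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             manifest = file.path(out_dir, "manifest.yaml"))
  loci_df <- do.call(rbind, lapply(names(results$loci), function(a) {
    l <- results$loci[[a]]
    data.frame(anchor_id = a, gene_id = l$gene_id, contig = l$contig,
               start = l$start, end = l$end, strand = l$strand,
               protein_id = l$protein_id, rank = l$rank,
               directon = l$directon,
               in_anchor_directon = l$in_anchor_directon,
               stringsAsFactors = FALSE)
  }))
  loci_df <- loci_df[order(loci_df$anchor_id, loci_df$start), ]
  write.table(loci_df, paths[["loci"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  prov <- results$clustering$provenance
  prov <- prov[order(prov$id), ]
  write.table(prov, paths[["clusters"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  prec <- results$precursors[order(results$precursors$cluster), ]
  write.table(prec, paths[["precursors"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  assoc <- results$associations
  assoc$passes_threshold <- assoc$family %in% results$associations_kept$family
  write.table(assoc, paths[["associations"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(results$clustering$tree)) {
    write_newick(results$clustering$tree, paths[["tree"]])
  } else {
    writeLines(paste0(names(results$clustering$clusters)[1L], ";"),
               paths[["tree"]])
  }
  writeLines(yaml::as.yaml(results$manifest), paths[["manifest"]])
  invisible(paths)
}
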