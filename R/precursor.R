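#' Filter homolog clusters to precursor candidates
#'
#' A cluster is a precursor candidate when (1) strictly more than
#' `majority` of its members are at most `max_len` residues long, and
#' (2) at least one member is encoded within `max_rank` genes of an
#' anchor (first and second neighbor in both directions by default).
#'
#' @param membership named integer vector: final homolog cluster per
#'   protein id.
#' @param seq_lengths named integer vector of protein lengths.
#' @param anchor_rank named numeric vector: minimum absolute neighbor
#'   rank of each protein relative to any anchor (`Inf` when the protein
#'   never occurs near an anchor).
#' @param max_len length cap in residues (default 150).
#' @param max_rank neighbor rank cap (default 2).
#' @param majority fraction that must satisfy the length cap (strict
#'   inequality; default 0.5).
#' @return data.frame per cluster: `cluster`, `n`, `frac_short`,
#'   `min_rank`, `kept`.
#' @export
candidate_filter <- function(membership, seq_lengths, anchor_rank,
                             max_len = 150, max_rank = 2, majority = 0.5) {
  ids <- names(membership)
  stopifnot(!is.null(ids), all(ids %in% names(seq_lengths)))
  rank <- anchor_rank[ids]
  rank[is.na(rank)] <- Inf
  out <- do.call(rbind, lapply(split(ids, membership[ids]), function(mem) {
    fs <- mean(seq_lengths[mem] <= max_len)
    mr <- min(rank[mem])
    data.frame(n = length(mem), frac_short = fs, min_rank = mr,
               kept = fs > majority && mr <= max_rank)
  }))
  out <- cbind(cluster = as.integer(rownames(out)), out)
  rownames(out) <- NULL
  out
}

#' Conserved small-residue doublets in a cluster alignment
#'
#' Operationalizes the "conserved doublet of small amino acids": a pair
#' of adjacent alignment columns, each with homogeneity at or above
#' `min_homog` and consensus residue in the small set; with
#' `require_gly` at least one consensus residue must be glycine.
#'
#' @param profile a [consensus_profile][derive_consensus].
#' @param small_set small residues (default G, A, S, C, E).
#' @param min_homog per-column homogeneity floor (default 0.5).
#' @param require_gly require a G in the doublet.
#' @return data.frame with columns `col1`, `col2` (alignment columns)
#'   and `doublet`.
#' @export
conserved_doublet <- function(profile, small_set = small_residue_set(),
                              min_homog = 0.5, require_gly = FALSE) {
  stopifnot(inherits(profile, "consensus_profile"))
  cons <- strsplit(profile$raw_consensus, "")[[1]]
  h <- profile$homogeneity
  ok <- cons %in% small_set & h >= min_homog
  n <- length(cons)
  res <- data.frame(col1 = integer(0), col2 = integer(0),
                    doublet = character(0), stringsAsFactors = FALSE)
  if (n < 2L) return(res)
  for (i in seq_len(n - 1L)) {
    if (ok[i] && ok[i + 1L]) {
      if (require_gly && !("G" %in% cons[c(i, i + 1L)])) next
      res <- rbind(res, data.frame(col1 = i, col2 = i + 1L,
                                   doublet = paste0(cons[i], cons[i + 1L]),
                                   stringsAsFactors = FALSE))
    }
  }
  res
}

#' Map bond-forming residue candidates on a consensus
#'
#' Positions in the core region whose (unmasked) consensus residue is a
#' lactone/lactam bond candidate (Ser, Thr, Asp, Glu, Lys) and whose
#' homogeneity reaches `min_homog` are reported as bond candidates;
#' conserved cysteines are reported separately as thioether (sulfur
#' donor) candidates. Masked (`x`) positions are never reported.
#'
#' @param profile a [consensus_profile][derive_consensus].
#' @param core_region optional `c(from, to)` alignment-column range; by
#'   default the columns after the last conserved small-residue doublet
#'   (the presumed cleavage site), or the whole consensus if none.
#' @param min_homog homogeneity floor (default 0.5).
#' @return list with data.frames `bond_candidates` and
#'   `thioether_candidates` (`position`, `residue`).
#' @export
map_bond_residues <- function(profile, core_region = NULL, min_homog = 0.5) {
  stopifnot(inherits(profile, "consensus_profile"))
  cons <- strsplit(profile$consensus, "")[[1]]
  h <- profile$homogeneity
  n <- length(cons)
  if (is.null(core_region)) {
    dbl <- conserved_doublet(profile)
    core_region <- if (nrow(dbl) > 0L && max(dbl$col2) < n) {
      c(max(dbl$col2) + 1L, n)
    } else c(1L, n)
  }
  span <- seq(core_region[1L], core_region[2L])
  sel <- function(set) {
    i <- span[cons[span] %in% set & h[span] >= min_homog]
    data.frame(position = i, residue = cons[i], stringsAsFactors = FALSE)
  }
  list(bond_candidates = sel(c("S", "T", "D", "E", "K")),
       thioether_candidates = sel("C"))
}

#' Classify a precursor cluster as known, new, candidate or rejected
#'
#' The decision table applied cluster-wide: **known** if any member
#' falls in the same 50%-identity/50%-coverage single-linkage component
#' as a reference precursor, or perfectly matches a library motif, or
#' carries a precursor annotation; otherwise **new** if the cluster
#' passed the candidate filter and its alignment shows a conserved
#' small-residue doublet; otherwise **candidate** if some member carries
#' both a GG-like doublet and the leader motif within the N-terminal 30
#' residues; otherwise **rejected**.
#'
#' @param seqs named character vector: the cluster's member sequences.
#' @param profile the cluster's [consensus_profile][derive_consensus].
#' @param passed_filter did the cluster pass [candidate_filter()]?
#' @param reference_seqs optional named character vector of reference
#'   precursors.
#' @param motif_library optional list of [motif_pattern]s (default
#'   [graspetide_motifs()]).
#' @param annotations optional character vector of member ids annotated
#'   as precursors.
#' @param ref_id_thr,ref_cov_thr linkage thresholds for the reference
#'   comparison (default 0.5/0.5).
#' @param nterm window used for the GG + leader candidate rule.
#' @param matrix substitution matrix.
#' @return a `precursor_call`: list with `status`, `evidence` (named
#'   logical vector), `bond_candidates`, `thioether_candidates`.
#' @export
classify_precursor <- function(seqs, profile, passed_filter,
                               reference_seqs = NULL,
                               motif_library = graspetide_motifs(),
                               annotations = NULL,
                               ref_id_thr = 0.5, ref_cov_thr = 0.5,
                               nterm = 30, matrix = blosum62()) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  ref_overlap <- FALSE
  if (!is.null(reference_seqs) && length(reference_seqs) > 0L) {
    pool <- c(seqs, reference_seqs)
    comp <- linkage_identity_coverage_cluster(pool, ref_id_thr, ref_cov_thr,
                                              matrix)
    ref_overlap <- any(comp[names(seqs)] %in% comp[names(reference_seqs)])
  }
  motif_match <- FALSE
  if (!is.null(motif_library) && length(motif_library) > 0L) {
    motif_match <- any(vapply(seqs, function(s)
      nrow(match_motif_library(s, motif_library)) > 0L, TRUE))
  }
  annotated <- !is.null(annotations) && any(names(seqs) %in% annotations)
  dbl <- conserved_doublet(profile)
  has_doublet <- nrow(dbl) > 0L
  gg_leader_nterm <- any(vapply(seqs, function(s) {
    gg <- scan_gg_motif(s)
    lead <- scan_leader_motif(s, window = nterm)
    any(gg$start <= nterm) && nrow(lead) > 0L
  }, TRUE))
  evidence <- c(ref_overlap = ref_overlap, motif_match = motif_match,
                annotated = annotated, passed_filter = isTRUE(passed_filter),
                conserved_doublet = has_doublet,
                gg_leader_nterm = gg_leader_nterm)
  status <- precursor_status(evidence)
  bonds <- map_bond_residues(profile)
  structure(list(status = status, evidence = evidence,
                 conserved_doublets = dbl,
                 bond_candidates = bonds$bond_candidates,
                 thioether_candidates = bonds$thioether_candidates),
            class = "precursor_call")
}

# the pure decision table: status from evidence flags alone
precursor_status <- function(evidence) {
  if (evidence[["ref_overlap"]] || evidence[["motif_match"]] ||
      evidence[["annotated"]]) {
    "known"
  } else if (evidence[["passed_filter"]] && evidence[["conserved_doublet"]]) {
    "new"
  } else if (evidence[["gg_leader_nterm"]]) {
    "candidate"
  } else {
    "rejected"
  }
}

#' @export
print.precursor_call <- function(x, ...) {
  cat("Precursor call:", x$status, "\n")
  ev <- names(x$evidence)[x$evidence]
  cat("  evidence:", if (length(ev)) paste(ev, collapse = ", ") else "none",
      "\n")
  if (nrow(x$bond_candidates) > 0L) {
    cat("  bond candidates:",
        paste(sprintf("%d:%s", x$bond_candidates$position,
                      x$bond_candidates$residue), collapse = ", "), "\n")
  }
  invisible(x)
}
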