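#' Position-specific scoring profile from a multiple alignment
#'
#' Builds a position-by-residue score table: entry (i, r) is the mean
#' substitution score of residue r against the non-gap residues in
#' alignment column i. All-gap columns are dropped. Together with
#' [profile_score()] this is the profile-vs-consensus scoring engine used
#' to compare homolog clusters.
#'
#' @param m a [protein_msa][new_msa] (or a
#'   [consensus_profile][derive_consensus], whose source alignment is
#'   used).
#' @param matrix substitution matrix, default [blosum62()].
#' @param gap_open,gap_extend affine gap penalties applied when the
#'   profile is aligned to a sequence.
#' @return a `scored_profile`: list with `scores` (columns x 21 residue
#'   alphabet, `X` scoring 0), `gap_open`, `gap_extend`.
#' @export
scored_profile <- function(m, matrix = blosum62(), gap_open = 11,
                           gap_extend = 1) {
  if (inherits(m, "consensus_profile")) m <- m$source
  stopifnot(inherits(m, "protein_msa"))
  mat <- msa_matrix(m)
  mm <- unclass(matrix)
  cols <- which(colSums(mat != "-") > 0L)
  if (length(cols) == 0L) stop("empty profile: alignment has no residue columns")
  scores <- t(vapply(cols, function(j) {
    res <- mat[, j]; res <- res[res != "-"]
    rowMeans(mm[AA21, res, drop = FALSE])
  }, numeric(21L)))
  colnames(scores) <- AA21
  structure(list(scores = scores, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scored_profile")
}

#' Best local profile-to-sequence alignment score
#'
#' Aligns a [scored_profile] to a sequence under the profile's affine gap
#' model and returns the best local score (0 if nothing scores
#' positively). Self-scores for cluster comparison are defined as the
#' profile scored against its own consensus sequence.
#'
#' @param p a `scored_profile`.
#' @param s a protein sequence (may contain `X`, scoring 0).
#' @return numeric score.
#' @export
profile_score <- function(p, s) {
  stopifnot(inherits(p, "scored_profile"))
  if (nrow(p$scores) == 0L) stop("empty profile")
  idx <- aa_index(s)
  .cpp_profile_score(p$scores, idx, p$gap_open, p$gap_extend)
}

#' Consensus as a plain sequence
#'
#' Strips gap columns from a consensus string and maps masked `x`
#' positions to `X` (scored 0 everywhere) so the consensus can be fed to
#' sequence-level routines.
#'
#' @param profile a [consensus_profile][derive_consensus] or a consensus
#'   string.
#' @return a sequence string.
#' @export
consensus_sequence <- function(profile) {
  s <- if (inherits(profile, "consensus_profile")) profile$consensus else profile
  s <- gsub("-", "", s, fixed = TRUE)
  gsub("x", "X", s, fixed = TRUE)
}
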