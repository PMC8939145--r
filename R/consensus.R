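#' Derive a consensus profile from a multiple alignment
#'
#' For each alignment column the consensus residue is the amino acid with
#' the maximum sum of substitution-matrix scores against all (non-gap)
#' residues in the column, ties broken alphabetically by one-letter code.
#' Columns whose homogeneity falls below `h_consensus` are masked to
#' `"x"`; all-gap columns get `"-"` and homogeneity 0.
#'
#' Homogeneity of a column with consensus k* is
#' `clip((S_bar - S_rand) / (S_self - S_rand), 0, 1)` where `S_bar` is the
#' mean matrix score of k* against the column's residues, `S_self` is
#' `score(k*, k*)` and `S_rand` the mean score of k* against the uniform
#' residue distribution: 1 for a uniform column, near 0 for a random one.
#'
#' @param m a [protein_msa][new_msa].
#' @param matrix substitution matrix, default [blosum62()].
#' @param h_consensus mask threshold (default 0.5).
#' @return a `consensus_profile`: list with `consensus` (string over
#'   residues, `x`, `-`), `raw_consensus` (unmasked), `homogeneity` and
#'   `gap_fraction` vectors, and the source alignment.
#' @export
derive_consensus <- function(m, matrix = blosum62(), h_consensus = 0.5) {
  stopifnot(inherits(m, "protein_msa"))
  mat <- msa_matrix(m)
  core <- unclass(matrix)[AA20, AA20]
  ncol_m <- ncol(mat)
  cons <- character(ncol_m)
  homog <- numeric(ncol_m)
  gapf <- numeric(ncol_m)
  for (j in seq_len(ncol_m)) {
    col <- mat[, j]
    res <- col[col != "-"]
    gapf[j] <- 1 - length(res) / length(col)
    if (length(res) == 0L) {
      cons[j] <- "-"; homog[j] <- 0
      next
    }
    cons[j] <- consensus_residue(res, matrix)
    homog[j] <- column_homogeneity(res, cons[j], matrix)
  }
  masked <- cons
  masked[cons != "-" & homog < h_consensus] <- "x"
  structure(list(consensus = paste(masked, collapse = ""),
                 raw_consensus = paste(cons, collapse = ""),
                 homogeneity = homog, gap_fraction = gapf,
                 h_consensus = h_consensus, source = m),
            class = "consensus_profile")
}

# argmax_k sum_i score(k, a_i) over the 20 standard residues;
# alphabetical tie-break (AA20 is sorted, which.max takes the first)
consensus_residue <- function(residues, matrix = blosum62()) {
  sc <- unclass(matrix)[AA20, residues, drop = FALSE]
  AA20[which.max(rowSums(sc))]
}

# Column conservation in [0,1] for consensus k*. Kept as a single small
# function so an alternative normalization can be swapped in.
column_homogeneity <- function(residues, kstar, matrix = blosum62()) {
  mm <- unclass(matrix)
  s_bar <- mean(mm[kstar, residues])
  s_self <- mm[kstar, kstar]
  s_rand <- mean(mm[kstar, AA20])
  h <- (s_bar - s_rand) / (s_self - s_rand)
  min(max(h, 0), 1)
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("Consensus profile (", nchar(x$consensus), " columns)\n", sep = "")
  cat("  ", substr(x$consensus, 1, 70), "\n", sep = "")
  invisible(x)
}

#' Filter alignment columns by gap fraction and homogeneity
#'
#' Retains exactly the columns with gap fraction below `max_gap` and
#' homogeneity above `min_homog` (the defaults implement the usual
#' pre-phylogeny filter: fewer than 50% gaps, homogeneity above 0.1).
#'
#' @param m a [protein_msa][new_msa].
#' @param profile the [consensus_profile][derive_consensus] derived from
#'   `m` (supplies per-column homogeneity and gap fractions).
#' @param max_gap columns with gap fraction `>= max_gap` are dropped.
#' @param min_homog columns with homogeneity `<= min_homog` are dropped.
#' @return a `protein_msa` of the retained columns, with attributes
#'   `kept_columns` (index map into the input) and `empty` (TRUE, with a
#'   warning, if nothing survives).
#' @export
filter_alignment <- function(m, profile = derive_consensus(m),
                             max_gap = 0.5, min_homog = 0.1) {
  stopifnot(inherits(m, "protein_msa"), inherits(profile, "consensus_profile"))
  if (length(profile$homogeneity) != m$column_count) {
    stop("profile was not derived from this alignment (column count differs)")
  }
  keep <- which(profile$gap_fraction < max_gap & profile$homogeneity > min_homog)
  mat <- msa_matrix(m)[, keep, drop = FALSE]
  rows <- if (length(keep) == 0L) rep("", length(m$ids)) else
    apply(mat, 1L, paste, collapse = "")
  out <- structure(list(ids = m$ids, rows = unname(rows),
                        column_count = length(keep)),
                   class = "protein_msa")
  attr(out, "kept_columns") <- keep
  if (length(keep) == 0L) {
    warning("no columns survive the gap/homogeneity filter")
    attr(out, "empty") <- TRUE
  } else {
    attr(out, "empty") <- FALSE
  }
  out
}
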