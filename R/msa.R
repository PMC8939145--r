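#' Construct a multiple alignment
#'
#' A light container for an aligned set of protein sequences: unique
#' member ids and equal-length gapped rows.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param rows character vector of gapped strings, one per id, all the
#'   same length.
#' @return a `protein_msa` object.
#' @export
new_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(ids) >= 1L)
  if (anyDuplicated(ids)) stop("duplicate member ids in alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length")
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 column_count = w),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x$ids), x$column_count))
  for (i in seq_len(min(6L, length(x$ids)))) {
    cat(sprintf("  %-12s %s\n", x$ids[i],
                substr(x$rows[i], 1, min(60, x$column_count))))
  }
  if (length(x$ids) > 6L) cat("  ...\n")
  invisible(x)
}

# alignment as a character matrix (rows = members, cols = columns)
msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$rows, ""))
}

#' Align a set of sequences (center-star progressive alignment)
#'
#' Deterministic multiple alignment built from the package's own pairwise
#' aligner: the longest sequence (ties by id) is the center; every other
#' member is globally aligned to it and the pairwise gap patterns are
#' merged ("once a gap, always a gap"). Adequate for the within-cluster
#' alignments this pipeline consumes; an external aligner can be slotted
#' in by constructing [new_msa()] directly from its output.
#'
#' @param seqs named character vector of protein sequences.
#' @param matrix substitution matrix, default [blosum62()].
#' @param gap_open,gap_extend affine gap penalties.
#' @return a `protein_msa` whose rows cover exactly `names(seqs)`.
#' @export
align_msa <- function(seqs, matrix = blosum62(), gap_open = 11,
                      gap_extend = 1) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) return(new_msa(names(seqs), unname(seqs)))
  orig_names <- names(seqs)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  center_id <- names(seqs)[1L]
  master <- strsplit(seqs[[1L]], "")[[1]]      # center row, gaps accrue
  rows <- list(strsplit(seqs[[1L]], "")[[1]])
  names(rows) <- center_id
  for (k in seq_along(seqs)[-1L]) {
    p <- align_pair(seqs[[1L]], seqs[[k]], matrix, mode = "global",
                    gap_open = gap_open, gap_extend = gap_extend)
    c_aln <- strsplit(p$aligned_a, "")[[1]]
    s_aln <- strsplit(p$aligned_b, "")[[1]]
    # merge the new pairwise gap pattern into the master columns
    i <- 1L; j <- 1L
    new_master <- character(0)
    take_old <- logical(0)   # TRUE: column existed in master
    take_new <- logical(0)   # TRUE: column exists in the pairwise aln
    nm <- length(master); np <- length(c_aln)
    while (i <= nm || j <= np) {
      if (i <= nm && j <= np && master[i] != "-" && c_aln[j] != "-") {
        new_master <- c(new_master, master[i])
        take_old <- c(take_old, TRUE); take_new <- c(take_new, TRUE)
        i <- i + 1L; j <- j + 1L
      } else if (i <= nm && master[i] == "-") {
        new_master <- c(new_master, "-")
        take_old <- c(take_old, TRUE); take_new <- c(take_new, FALSE)
        i <- i + 1L
      } else {
        new_master <- c(new_master, "-")
        take_old <- c(take_old, FALSE); take_new <- c(take_new, TRUE)
        j <- j + 1L
      }
    }
    w <- length(new_master)
    rows <- lapply(rows, function(r) {
      out <- rep("-", w); out[take_old] <- r; out
    })
    new_row <- rep("-", w); new_row[take_new] <- s_aln
    rows[[names(seqs)[k]]] <- new_row
    master <- new_master
  }
  # restore the caller's id order
  rows <- rows[orig_names]
  new_msa(names(rows), vapply(rows, paste, "", collapse = ""))
}

# drop all-gap columns (can arise after subsetting)
drop_gap_columns <- function(m) {
  mat <- msa_matrix(m)
  keep <- colSums(mat != "-") > 0L
  new_msa(m$ids, apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""))
}
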