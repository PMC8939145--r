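#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix format distributed with BLAST
#' (comment lines starting with `#`, a header row of one-letter codes, one
#' labelled row per residue). Only the 20 standard amino acids are kept;
#' an `X` (unknown) row and column scoring 0 against everything is
#' appended, so sequences containing `X` contribute nothing to alignment
#' scores.
#'
#' @param path path to a matrix text file.
#' @param name label stored with the matrix (defaults to the file name).
#' @return a `subst_matrix`: an integer matrix over `A..Y,X` with `name`
#'   and class attributes.
#' @export
read_substitution_matrix <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[[`, "", 1L)
  vals <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(vals) <- list(labels, header)
  keep <- AA20
  missing <- setdiff(keep, intersect(rownames(vals), colnames(vals)))
  if (length(missing) > 0) {
    stop("matrix file lacks standard residues: ", paste(missing, collapse = ", "))
  }
  m <- matrix(0L, 21L, 21L, dimnames = list(AA21, AA21))
  m[keep, keep] <- as.integer(vals[keep, keep])
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix is not symmetric")
  structure(m, name = name, class = c("subst_matrix", class(m)))
}

#' The bundled BLOSUM62 matrix
#'
#' Loads (and caches) the BLOSUM62 substitution matrix shipped with the
#' package, in the form used by every scoring routine: 20 standard
#' residues plus an `X` column of zeros.
#'
#' @return a `subst_matrix`.
#' @export
blosum62 <- function() {
  if (is.null(.gm_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "graspmine")
    .gm_cache$blosum62 <- read_substitution_matrix(path, name = "BLOSUM62")
  }
  .gm_cache$blosum62
}

.gm_cache <- new.env(parent = emptyenv())

#' @export
print.subst_matrix <- function(x, ...) {
  cat("Substitution matrix:", attr(x, "name"), "\n")
  print(unclass(x)[1:21, 1:21])
  invisible(x)
}

# map a residue string to 1-based indices into AA21; errors name the
# offending symbol
aa_index <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("empty ", what)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, AA21)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("non-alphabet character(s) in ", what, ": ",
         paste(dQuote(bad, FALSE), collapse = ", "))
  }
  idx
}

aa_unindex <- function(idx) {
  out <- character(length(idx))
  out[idx == 0L] <- "-"
  out[idx > 0L] <- AA21[idx[idx > 0L]]
  paste(out, collapse = "")
}
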