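#' Read a gene feature table
#'
#' Two dialects are supported. The simple 6-column TSV dialect has
#' columns `contig`, `gene_id`, `start`, `end`, `strand`, `protein_id`
#' (1-based inclusive coordinates, strand `+`/`-`). GFF3 files are read
#' through rtracklayer; CDS features are kept, `gene_id` comes from the
#' `ID` attribute and `protein_id` from a `protein_id` attribute (falling
#' back to `ID`).
#'
#' @param path file path; format guessed from the extension unless given.
#' @param format `"tsv"` or `"gff3"`.
#' @return a `gene_features` data.frame with the six columns above,
#'   sorted by contig then start.
#' @export
read_features <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    pid <- if (!is.null(gr$protein_id)) gr$protein_id else gr$ID
    df <- data.frame(
      contig = as.character(GenomicRanges::seqnames(gr)),
      gene_id = as.character(gr$ID),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      protein_id = as.character(pid),
      stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("contig", "gene_id", "start", "end", "strand", "protein_id")
    if (!all(need %in% names(df))) {
      stop("feature table must have columns: ", paste(need, collapse = ", "))
    }
    df <- df[need]
  }
  validate_features(df)
}

validate_features <- function(df) {
  stopifnot(is.data.frame(df))
  if (any(df$start >= df$end)) stop("feature with start >= end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id")
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Write a gene feature table (6-column TSV dialect)
#'
#' @param features a `gene_features` data.frame.
#' @param path output path.
#' @export
write_features <- function(features, path) {
  write.table(features[c("contig", "gene_id", "start", "end", "strand",
                         "protein_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write features as GFF3
#'
#' Emits one CDS feature per gene with `ID` and `protein_id` attributes.
#'
#' @param features a `gene_features` data.frame.
#' @param path output path.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand,
    type = "CDS", ID = features$gene_id, protein_id = features$protein_id,
    phase = 0L)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the gene neighborhood of an anchor gene
#'
#' Collects up to `window` genes on each side of the anchor on its
#' contig, assigning each gene a signed neighbor rank (negative upstream
#' in coordinate order, 0 for the anchor itself). Truncation at contig
#' edges is recorded.
#'
#' @param features a `gene_features` data.frame.
#' @param anchor_id the anchor's `gene_id`.
#' @param window maximum neighbor rank on each side (default 10).
#' @return a `locus`: the neighborhood rows of `features` plus a `rank`
#'   column, with attributes `anchor_id` and `truncated` (logical pair
#'   `upstream`/`downstream`).
#' @export
extract_neighborhood <- function(features, anchor_id, window = 10) {
  stopifnot(window >= 0)
  hit <- which(features$gene_id == anchor_id)
  if (length(hit) != 1L) stop("anchor gene not found: ", anchor_id)
  contig <- features$contig[hit]
  block <- features[features$contig == contig, , drop = FALSE]
  block <- block[order(block$start), , drop = FALSE]
  a <- which(block$gene_id == anchor_id)
  lo <- max(1L, a - window); hi <- min(nrow(block), a + window)
  out <- block[lo:hi, , drop = FALSE]
  out$rank <- seq(lo, hi) - a
  rownames(out) <- NULL
  class(out) <- c("locus", "data.frame")
  attr(out, "anchor_id") <- anchor_id
  attr(out, "truncated") <- c(upstream = (a - window) < 1L,
                              downstream = (a + window) > nrow(block))
  out
}

#' Group a locus into directons
#'
#' A directon is a maximal run of adjacent same-strand genes whose
#' successive intergenic gaps do not exceed `max_gap` bases — the operon
#' proxy used for guilt-by-association statistics. The directon
#' containing the anchor gene is flagged.
#'
#' @param locus a [locus][extract_neighborhood] (genes sorted by start).
#' @param max_gap maximum intergenic gap in bases (default 100).
#' @return the locus data.frame with a `directon` integer column and a
#'   logical `in_anchor_directon` column.
#' @export
assemble_directons <- function(locus, max_gap = 100) {
  stopifnot(nrow(locus) >= 1L)
  if (is.unsorted(locus$start)) stop("locus genes must be sorted by start")
  n <- nrow(locus)
  directon <- integer(n)
  directon[1L] <- 1L
  if (n > 1L) {
    for (i in seq(2L, n)) {
      gap <- locus$start[i] - locus$end[i - 1L] - 1L
      same <- locus$strand[i] == locus$strand[i - 1L] && gap <= max_gap
      directon[i] <- if (same) directon[i - 1L] else directon[i - 1L] + 1L
    }
  }
  locus$directon <- directon
  anchor <- attr(locus, "anchor_id")
  anchor_dir <- directon[locus$gene_id == anchor]
  locus$in_anchor_directon <- if (length(anchor_dir) == 1L) {
    directon == anchor_dir
  } else rep(NA, n)
  locus
}
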