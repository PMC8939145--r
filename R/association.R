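#' Redundancy weights for anchor loci
#'
#' Near-identical loci (GenBank redundancy) would otherwise dominate
#' co-occurrence counts, so each locus is weighted by the reciprocal of
#' the size of its anchor's redundancy group — the tier-1 (90% identity)
#' cluster of the anchor protein. Weights within a group sum to 1, and
#' the total weight equals the number of distinct groups.
#'
#' @param locus_ids character vector of locus identifiers.
#' @param redundancy_group vector (parallel to `locus_ids`) assigning
#'   each locus its anchor redundancy group.
#' @return data.frame: `locus_id`, `redundancy_group`, `weight`.
#' @export
locus_weights <- function(locus_ids, redundancy_group) {
  stopifnot(length(locus_ids) == length(redundancy_group))
  size <- table(redundancy_group)
  data.frame(locus_id = locus_ids,
             redundancy_group = redundancy_group,
             weight = 1 / as.numeric(size[as.character(redundancy_group)]),
             stringsAsFactors = FALSE)
}

#' Guilt-by-association statistics over anchor directons
#'
#' For every non-anchor gene family, counts the loci whose anchor
#' directon contains at least one member (`raw_count`, a family counted
#' at most once per locus) and the redundancy-weighted fraction of loci
#' (`weighted_frequency` = sum of weights of the loci containing the
#' family divided by the total locus weight).
#'
#' @param locus_families named list: per locus id, the character vector
#'   of family ids present in the anchor directon (excluding the anchor
#'   family itself).
#' @param weights data.frame from [locus_weights()] covering every locus.
#' @return data.frame of association records sorted by
#'   `weighted_frequency` descending: `family`, `raw_count`,
#'   `weighted_frequency`.
#' @export
weighted_association <- function(locus_families, weights) {
  stopifnot(all(names(locus_families) %in% weights$locus_id))
  w <- setNames(weights$weight, weights$locus_id)
  total <- sum(w[names(locus_families)])
  fams <- sort(unique(unlist(locus_families)))
  out <- do.call(rbind, lapply(fams, function(f) {
    has <- vapply(locus_families, function(x) f %in% x, TRUE)
    data.frame(family = f, raw_count = sum(has),
               weighted_frequency = sum(w[names(locus_families)][has]) / total,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(family = character(0), raw_count = integer(0),
                      weighted_frequency = numeric(0))
  }
  out <- out[order(-out$weighted_frequency, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the reporting thresholds to association records
#'
#' Keeps families present in more than `min_loci` loci and in at least
#' `min_wfreq` of the independent (weighted) observations, sorted by
#' weighted frequency descending.
#'
#' @param records data.frame from [weighted_association()].
#' @param min_loci raw count must strictly exceed this (default 20).
#' @param min_wfreq weighted frequency floor, a fraction (default 0.01).
#' @return filtered, sorted data.frame with a `passes_threshold` column
#'   (all TRUE).
#' @export
filter_associations <- function(records, min_loci = 20, min_wfreq = 0.01) {
  keep <- records$raw_count > min_loci & records$weighted_frequency >= min_wfreq
  out <- records[keep, , drop = FALSE]
  out <- out[order(-out$weighted_frequency, out$family), , drop = FALSE]
  out$passes_threshold <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
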