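#' Greedy centroid clustering at an identity threshold
#'
#' UCLUST-style greedy clustering: sequences are processed in a
#' deterministic order (length descending, then id ascending); each is
#' assigned to the first existing centroid with global identity at or
#' above the threshold (shorter-sequence denominator), otherwise it
#' founds a new centroid. Composing two passes (0.9, then 0.5 on the
#' representatives) gives the two-tier scheme used by [cluster_homologs()].
#'
#' @param seqs named character vector of protein sequences.
#' @param threshold identity threshold in (0, 1].
#' @param matrix substitution matrix.
#' @param gap_open,gap_extend affine gap penalties of the identity
#'   alignments.
#' @param accel use the deterministic accelerations of the clustering
#'   loop (4-mer prescreen of candidate pairs and a diagonal shortcut
#'   for near-identical equal-length pairs, as heuristic identity
#'   clusterers do); `FALSE` forces a full alignment for every candidate
#'   pair.
#' @return list with `membership` (named integer vector, cluster index
#'   per sequence) and `representatives` (centroid id per cluster).
#' @export
greedy_identity_cluster <- function(seqs, threshold, matrix = blosum62(),
                                    gap_open = 11, gap_extend = 1,
                                    accel = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(seqs) == 0L) {
    return(list(membership = setNames(integer(0), character(0)),
                representatives = character(0)))
  }
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  idx <- lapply(unname(seqs), aa_index)
  membership <- .cpp_greedy_cluster(idx, threshold, unclass(matrix),
                                    gap_open, gap_extend, accel)
  names(membership) <- names(seqs)
  reps <- names(seqs)[!duplicated(membership)]
  list(membership = membership, representatives = reps)
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

#' Single-linkage clustering by identity and mutual coverage
#'
#' Connects two sequences when their global identity (shorter-sequence
#' denominator) reaches `id_thr` and the coverage of *both* sequences
#' reaches `cov_thr`; clusters are the connected components
#' (BLASTCLUST-like, used for the 80%/80% and 50%/50% comparisons
#' against reference sets).
#'
#' @param seqs named character vector.
#' @param id_thr,cov_thr thresholds in (0, 1].
#' @param matrix substitution matrix.
#' @return named integer vector: component index per sequence, numbered
#'   by first appearance in input order.
#' @export
linkage_identity_coverage_cluster <- function(seqs, id_thr, cov_thr,
                                              matrix = blosum62()) {
  stopifnot(id_thr > 0, id_thr <= 1, cov_thr > 0, cov_thr <= 1)
  n <- length(seqs)
  if (n == 0L) return(setNames(integer(0), character(0)))
  parent <- uf_new(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        idt <- seq_identity(seqs[[i]], seqs[[j]], matrix)
        if (idt$identity >= id_thr && min(idt$coverage) >= cov_thr) {
          parent <- uf_union(parent, i, j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  comp <- match(roots, unique(roots))
  setNames(comp, names(seqs))
}

#' Convert cluster cross-scores to a distance
#'
#' `d = -ln(max(s_AB, s_BA) / min(s_AA, s_BB))`, clamped to 0 when the
#' best cross-score exceeds the smaller self-score (a distance cannot be
#' negative). Scores must be positive; callers clamp raw alignment scores
#' to a floor of 1 beforehand.
#'
#' @param s_ab,s_ba cross-scores between clusters A and B (either
#'   direction of the profile-vs-consensus comparison).
#' @param s_aa,s_bb self-scores.
#' @return non-negative distance (symmetric in A and B).
#' @export
score_to_distance <- function(s_ab, s_ba, s_aa, s_bb) {
  if (any(c(s_ab, s_ba, s_aa, s_bb) <= 0)) {
    stop("all scores must be positive (apply the score floor first)")
  }
  max(0, -log(max(s_ab, s_ba) / min(s_aa, s_bb)))
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair group method with arithmetic mean: the
#' closest pair of clusters is merged at node height d/2 and distances to
#' the merged cluster are size-weighted means. Equal minima are resolved
#' by the lexicographically smallest pair of smallest-member labels, so
#' the construction is deterministic.
#'
#' @param d a symmetric numeric matrix with zero diagonal and dimnames,
#'   or a [stats::dist] object.
#' @return an `upgma_tree`: list with hclust-style `merge`, `node_height`
#'   (ultrametric height of each internal node, i.e. d/2 at the merge)
#'   and `labels`.
#' @export
upgma_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  n <- nrow(d)
  if (n == 1L) {
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          node_height = numeric(0), labels = labels),
                     class = "upgma_tree"))
  }
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  active <- as.list(seq_len(n))         # member leaf indices per cluster
  node <- -seq_len(n)                   # hclust coding of each active cluster
  sizes <- rep(1L, n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  node_height <- numeric(n - 1L)
  key <- vapply(active, function(m) min(labels[m]), "")
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    dm <- Inf; bi <- 0L; bj <- 0L; bkey <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        pk <- sort(c(key[i], key[j]))
        if (D[i, j] < dm - 1e-15 ||
            (abs(D[i, j] - dm) <= 1e-15 && !is.null(bkey) &&
             (pk[1] < bkey[1] || (pk[1] == bkey[1] && pk[2] < bkey[2])))) {
          dm <- min(dm, D[i, j]); bi <- i; bj <- j; bkey <- pk
        }
      }
    }
    merge[step, ] <- c(node[bi], node[bj])
    node_height[step] <- dm / 2
    # size-weighted mean distances to the merged cluster
    newd <- (sizes[bi] * D[bi, ] + sizes[bj] * D[bj, ]) / (sizes[bi] + sizes[bj])
    keep <- setdiff(seq_len(k), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(c(active[[bi]], active[[bj]])))
    node <- c(node[keep], step)
    sizes <- c(sizes[keep], sizes[bi] + sizes[bj])
    key <- c(key[keep], min(bkey))
  }
  structure(list(merge = merge, node_height = node_height, labels = labels),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %g\n", length(x$labels),
              if (length(x$node_height)) max(x$node_height) else 0))
  invisible(x)
}

# leaf order by traversal, for hclust conversion
.tree_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  if (nrow(merge) == 0L) return(1L)
  walk(nrow(merge))
}

#' @export
as.hclust.upgma_tree <- function(x, ...) {
  if (nrow(x$merge) == 0L) stop("cannot convert a single-leaf tree to hclust")
  structure(list(merge = x$merge, height = 2 * x$node_height,
                 order = .tree_leaf_order(x$merge), labels = x$labels,
                 method = "average"),
            class = "hclust")
}

#' Cophenetic distances of an ultrametric tree
#'
#' @param t an [upgma_tree].
#' @return a symmetric matrix of cophenetic distances (twice the height of
#'   the lowest common ancestor).
#' @export
cophenetic_upgma <- function(t) {
  n <- length(t$labels)
  if (n == 1L) return(matrix(0, 1, 1, dimnames = list(t$labels, t$labels)))
  out <- as.matrix(stats::cophenetic(stats::as.hclust(t)))
  out[t$labels, t$labels]
}

#' Write an ultrametric tree as newick
#'
#' @param t an [upgma_tree].
#' @param path optional file path; when `NULL` the newick string is
#'   returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_newick <- function(t, path = NULL) {
  stopifnot(inherits(t, "upgma_tree"))
  if (nrow(t$merge) == 0L) {
    nwk <- paste0(t$labels, ";")
  } else {
    phy <- ape::as.phylo(stats::as.hclust(t))
    nwk <- ape::write.tree(phy)
  }
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Dissect an ultrametric tree at a depth cutoff
#'
#' Cuts the tree at a height threshold: every maximal subtree whose root
#' height does not exceed the cutoff becomes one cluster (a cutoff of 0
#' yields all singletons; a cutoff at or above the root height yields one
#' cluster). The default cutoff is `-ln(0.01) / 2`, the height at which
#' two clusters' best cross-score is 1% of the smaller self-score.
#'
#' @param t an [upgma_tree].
#' @param depth_cutoff height threshold in distance units.
#' @return named integer vector: cluster index per leaf, numbered in leaf
#'   label order of first occurrence.
#' @export
dissect_tree <- function(t, depth_cutoff = -log(0.01) / 2) {
  stopifnot(inherits(t, "upgma_tree"))
  n <- length(t$labels)
  parent <- uf_new(n)
  for (s in seq_len(nrow(t$merge))) {
    if (t$node_height[s] <= depth_cutoff) {
      mem <- .merge_leaves(t$merge, s)
      for (i in mem[-1]) parent <- uf_union(parent, mem[1], i)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  comp <- match(roots, unique(roots))
  setNames(comp, t$labels)
}

.merge_leaves <- function(merge, node) {
  walk <- function(nd) {
    if (nd < 0) return(-nd)
    c(walk(merge[nd, 1]), walk(merge[nd, 2]))
  }
  walk(node)
}

#' Full homolog clustering of a protein set
#'
#' The complete procedure: tier-1 greedy identity clustering (default
#' 0.9), tier-2 greedy clustering of the tier-1 representatives (default
#' 0.5), per-tier-2-cluster multiple alignment and consensus, all-vs-all
#' profile-vs-consensus cross-scoring with a score floor of 1, the
#' log-ratio score-to-distance transform, UPGMA construction and
#' depth-cutoff dissection. All sequences under the same dissected
#' subtree form one final cluster of homologs.
#'
#' @param seqs named character vector of protein sequences.
#' @param tier1,tier2 greedy identity thresholds.
#' @param depth_cutoff tree dissection height (default `-ln(0.01)/2`,
#'   about 2.30).
#' @param matrix substitution matrix.
#' @param gap_open,gap_extend affine gap penalties.
#' @param score_floor minimum score used in the distance ratio.
#' @param evalue_max significance gate on cross-scores: a cross-score
#'   whose Karlin-Altschul expect value (using `ka_lambda`, `ka_k`, the
#'   standard gapped BLOSUM62 11/1 constants) exceeds this bound is
#'   treated as "no hit" and replaced by `score_floor`, mirroring a
#'   profile search that only reports significant hits (default 1e-6,
#'   the usual profile-search inclusion threshold). Self-scores are
#'   never gated. Set to `Inf` to disable.
#' @param ka_lambda,ka_k Karlin-Altschul parameters for the gate.
#' @return list with `provenance` (data.frame: id, tier1, tier2, final),
#'   `clusters` (per tier-2 cluster: member ids, representative,
#'   alignment, consensus profile, scored profile), `tree` (the UPGMA
#'   `upgma_tree` over tier-2 clusters, NULL if fewer than 2), `scores`
#'   and `distances` matrices, and `final` (named integer vector over all
#'   sequence ids).
#' @export
cluster_homologs <- function(seqs, tier1 = 0.9, tier2 = 0.5,
                             depth_cutoff = -log(0.01) / 2,
                             matrix = blosum62(), gap_open = 11,
                             gap_extend = 1, score_floor = 1,
                             evalue_max = 1e-6, ka_lambda = 0.267,
                             ka_k = 0.041) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  t1 <- greedy_identity_cluster(seqs, tier1, matrix, gap_open, gap_extend)
  reps1 <- seqs[t1$representatives]
  t2 <- greedy_identity_cluster(reps1, tier2, matrix, gap_open, gap_extend)
  # tier-2 membership of every sequence, through its tier-1 representative
  t1_of <- t1$membership[names(seqs)]
  t2_of <- t2$membership[t1$representatives][t1_of]
  names(t2_of) <- names(seqs)
  n2 <- length(t2$representatives)
  cl_ids <- sprintf("C%03d", seq_len(n2))
  clusters <- lapply(seq_len(n2), function(k) {
    mem <- names(seqs)[t2_of == k]
    aln <- align_msa(seqs[mem], matrix, gap_open, gap_extend)
    prof <- derive_consensus(aln, matrix)
    list(cluster_id = cl_ids[k], member_ids = mem,
         representative_id = t2$representatives[k],
         alignment = aln, profile = prof,
         scored = scored_profile(aln, matrix, gap_open, gap_extend))
  })
  names(clusters) <- cl_ids
  if (n2 == 1L) {
    final_of_t2 <- setNames(1L, cl_ids)
    tree <- NULL; s <- NULL; d <- NULL
  } else {
    cons <- vapply(clusters, function(cl) consensus_sequence(cl$profile), "")
    s <- matrix(0, n2, n2, dimnames = list(cl_ids, cl_ids))
    for (i in seq_len(n2)) {
      for (j in seq_len(n2)) {
        sc <- profile_score(clusters[[i]]$scored, cons[[j]])
        if (i != j && is.finite(evalue_max)) {
          # chance expectation of the cross-score; non-significant
          # scores are treated as no hit (floored)
          mn <- nrow(clusters[[i]]$scored$scores) * nchar(cons[[j]])
          ev <- ka_k * mn * exp(-ka_lambda * sc)
          if (ev > evalue_max) sc <- score_floor
        }
        s[i, j] <- max(score_floor, sc)
      }
    }
    d <- matrix(0, n2, n2, dimnames = list(cl_ids, cl_ids))
    for (i in seq_len(n2 - 1L)) {
      for (j in seq(i + 1L, n2)) {
        d[i, j] <- d[j, i] <- score_to_distance(s[i, j], s[j, i],
                                                s[i, i], s[j, j])
      }
    }
    tree <- upgma_tree(d)
    final_of_t2 <- dissect_tree(tree, depth_cutoff)
  }
  final <- setNames(final_of_t2[cl_ids[t2_of]], names(seqs))
  provenance <- data.frame(id = names(seqs),
                           tier1 = unname(t1_of),
                           tier2 = unname(t2_of),
                           final = unname(final),
                           stringsAsFactors = FALSE)
  list(provenance = provenance, clusters = clusters, tree = tree,
       scores = s, distances = d, final = final,
       tier1 = t1, tier2 = t2)
}
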