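test_that("greedy clustering groups identical and separates dissimilar pairs", {
  s <- random_seq(40)
  r1 <- greedy_identity_cluster(c(a = s, b = s), 0.9)
  expect_equal(length(r1$representatives), 1L)
  half <- paste0(substr(s, 1, 20), random_seq(20))
  r2 <- greedy_identity_cluster(c(a = s, b = half), 0.9)
  expect_equal(length(r2$representatives), 2L)
})

test_that("greedy clustering is invariant to input order", {
  set.seed(19)
  s1 <- random_seq(40)
  seqs <- c(A = s1, B = s1, C = random_seq(40))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  parts <- lapply(perms, function(p) {
    r <- greedy_identity_cluster(seqs[p], 0.9)
    split(names(r$membership), r$membership)
  })
  for (p in parts[-1]) expect_equal(p, parts[[1]])
  expect_equal(sort(parts[[1]][[1]]), c("A", "B"))
})

test_that("greedy accelerations do not change the clustering of evolved families", {
  set.seed(23)
  seqs <- c(evolve_family(family_spec("F1", 60, 0.05, 6, "decoy")),
            evolve_family(family_spec("F2", 80, 0.05, 5, "decoy")),
            evolve_family(family_spec("F3", 45, 0.05, 4, "decoy")))
  for (thr in c(0.9, 0.5)) {
    fast <- greedy_identity_cluster(seqs, thr, accel = TRUE)
    slow <- greedy_identity_cluster(seqs, thr, accel = FALSE)
    expect_equal(fast$membership, slow$membership)
  }
})

test_that("linkage clustering respects identity chains and coverage gates", {
  s <- random_seq(40)
  b <- mutate_seq(s, 6)        # ~85% to s
  c2 <- mutate_seq(b, 6)       # ~85% to b, ~72% to s
  comp <- linkage_identity_coverage_cluster(c(A = s, B = b, C = c2),
                                            0.8, 0.8)
  expect_equal(length(unique(comp)), 1L)     # single linkage chains
  # a short peptide inside a long protein fails the long sequence's coverage
  long <- random_seq(100)
  short <- substr(long, 30, 49)
  comp2 <- linkage_identity_coverage_cluster(c(L = long, S = short), 0.8, 0.8)
  expect_equal(length(unique(comp2)), 2L)
  # but an identical pair at 80/80 is one component
  comp3 <- linkage_identity_coverage_cluster(c(A = s, B = s), 0.8, 0.8)
  expect_equal(length(unique(comp3)), 1L)
})

test_that("score-to-distance follows the log-ratio formula with clamping", {
  expect_equal(score_to_distance(100, 100, 100, 100), 0)
  expect_equal(score_to_distance(60, 50, 100, 100), -log(0.6))
  expect_equal(score_to_distance(120, 110, 100, 100), 0)
  expect_error(score_to_distance(0, 50, 100, 100), "positive")
})

test_that("score-to-distance is symmetric, non-negative and monotone", {
  grid <- expand.grid(ab = c(1, 10, 50, 90, 120), ba = c(1, 40, 80),
                      aa = c(100, 150), bb = c(90, 200))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d1 <- score_to_distance(g$ab, g$ba, g$aa, g$bb)
    d2 <- score_to_distance(g$ba, g$ab, g$bb, g$aa)
    expect_equal(d1, d2)
    expect_gte(d1, 0)
  }
  d_lo <- score_to_distance(10, 5, 100, 100)
  d_hi <- score_to_distance(50, 5, 100, 100)
  expect_gt(d_lo, d_hi)  # decreasing in the best cross-score
})

test_that("UPGMA reproduces hand-computed merges", {
  d1 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  t1 <- upgma_tree(d1)
  expect_equal(t1$node_height, 2)
  d2 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t2 <- upgma_tree(d2)
  expect_equal(t2$node_height, c(1, 4))
  expect_equal(unname(dissect_tree(t2, 2.3)), c(1, 1, 2))
})

test_that("UPGMA matches the naive average-linkage oracle on random matrices", {
  set.seed(29)
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    m <- matrix(runif(n * n, 1, 10), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    mine <- cophenetic_upgma(upgma_tree(m))
    oracle <- naive_upgma_cophenetic(m)
    expect_lt(max(abs(mine[letters[1:n], letters[1:n]] - oracle)), 1e-9)
  }
})

test_that("cophenetic distances reproduce ultrametric inputs exactly", {
  set.seed(31)
  for (rep in 1:20) {
    # build a random ultrametric by assigning merge heights on a random tree
    n <- 6
    hts <- sort(runif(n - 1, 0, 5))
    part <- as.list(seq_len(n))
    D <- matrix(0, n, n)
    for (s in seq_len(n - 1)) {
      pick <- sample(length(part), 2)
      for (a in part[[pick[1]]]) for (b in part[[pick[2]]]) {
        D[a, b] <- D[b, a] <- 2 * hts[s]
      }
      part[[pick[1]]] <- c(part[[pick[1]]], part[[pick[2]]])
      part[[pick[2]]] <- NULL
    }
    dimnames(D) <- list(letters[1:n], letters[1:n])
    t <- upgma_tree(D)
    expect_lt(max(abs(cophenetic_upgma(t)[letters[1:n], letters[1:n]] - D)),
              1e-9)
  }
})

test_that("tree dissection is exhaustive, disjoint and nested in the cutoff", {
  set.seed(37)
  n <- 8
  m <- matrix(runif(n * n, 1, 10), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:n], letters[1:n])
  t <- upgma_tree(m)
  expect_equal(sort(names(dissect_tree(t, 1))), sort(letters[1:n]))
  expect_equal(unname(dissect_tree(t, 0)), seq_len(n))       # singletons
  expect_equal(length(unique(dissect_tree(t, max(t$node_height)))), 1L)
  cuts <- sort(runif(4, 0, 5))
  for (i in seq_along(cuts)[-1]) {
    p1 <- dissect_tree(t, cuts[i - 1])
    p2 <- dissect_tree(t, cuts[i])
    # finer partition refines the coarser one
    for (cl in unique(p1)) {
      expect_equal(length(unique(p2[names(p1)[p1 == cl]])), 1L)
    }
  }
})

test_that("newick output round-trips through ape with matching heights", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- upgma_tree(d)
  phy <- ape::read.tree(text = write_newick(t))
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  coph <- ape::cophenetic.phylo(phy)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 8)
})

test_that("cluster_homologs recovers planted families and unites duplicates", {
  expect_equal(unname(cluster_homologs(c(one = random_seq(30)))$final), 1L)
  set.seed(43)
  fams <- list(evolve_family(family_spec("FA", 120, 0.04, 5, "ancillary")),
               evolve_family(family_spec("FB", 150, 0.04, 5, "ancillary")),
               evolve_family(family_spec("FC", 100, 0.04, 5, "ancillary")))
  seqs <- c(fams[[1]], fams[[2]], fams[[3]])
  truth <- rep(c("FA", "FB", "FC"), times = vapply(fams, length, 0L))
  ch <- cluster_homologs(seqs)
  expect_equal(mclust::adjustedRandIndex(ch$final, truth), 1)
  # exact duplicates always share a final cluster (tier-1 guarantee)
  dup <- c(seqs, dupX = unname(seqs[1]))
  ch2 <- cluster_homologs(dup)
  expect_equal(unname(ch2$final["dupX"]), unname(ch2$final[names(seqs)[1]]))
})

test_that("cluster_homologs is invariant to input order and id relabeling", {
  set.seed(47)
  seqs <- c(evolve_family(family_spec("FA", 80, 0.04, 4, "ancillary")),
            evolve_family(family_spec("FB", 95, 0.04, 4, "ancillary")))
  ch1 <- cluster_homologs(seqs)
  perm <- sample(length(seqs))
  ch2 <- cluster_homologs(seqs[perm])
  expect_equal(ch1$final[names(seqs)], ch2$final[names(seqs)])
  relab <- setNames(seqs, sprintf("z%02d", seq_along(seqs)))
  ch3 <- cluster_homologs(relab)
  m1 <- unname(ch1$final[names(seqs)])
  m3 <- unname(ch3$final[sprintf("z%02d", seq_along(seqs))])
  expect_equal(mclust::adjustedRandIndex(m1, m3), 1)
})
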