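test_that("global alignment scores identity and substitution cases", {
  expect_equal(align_pair("AAAA", "AAAA")$score, 16)
  expect_equal(align_pair("AAAA", "AATA")$score, 12)  # A/T scores 0
  p <- align_pair("MKVLT", "MKVLT")
  diag_sum <- sum(diag(blosum62())[strsplit("MKVLT", "")[[1]]])
  expect_equal(p$score, diag_sum)
})

test_that("self-alignment score equals the diagonal sum for random sequences", {
  set.seed(41)
  B <- blosum62()
  for (i in 1:20) {
    s <- random_seq(sample(5:60, 1))
    expect_equal(align_pair(s, s)$score,
                 sum(diag(B)[strsplit(s, "")[[1]]]))
  }
})

test_that("local alignment of incompatible sequences is empty with score 0", {
  p <- align_pair("KKKK", "WWWW", mode = "local")
  expect_equal(p$score, 0)
  expect_equal(nchar(p$aligned_a), 0L)
})

test_that("alignment scores match an independent implementation on random pairs", {
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(7)
  for (i in 1:25) {
    a <- random_seq(sample(8:50, 1)); b <- random_seq(sample(8:50, 1))
    expect_equal(align_pair(a, b)$score,
                 Biostrings::score(Biostrings::pairwiseAlignment(
                   a, b, substitutionMatrix = BLOSUM62,
                   gapOpening = 11, gapExtension = 1, type = "global")))
    expect_equal(align_pair(a, b, mode = "local")$score,
                 max(0, Biostrings::score(Biostrings::pairwiseAlignment(
                   a, b, substitutionMatrix = BLOSUM62,
                   gapOpening = 11, gapExtension = 1, type = "local"))))
  }
})

test_that("alignment rejects empty or non-alphabet input, naming the symbol", {
  expect_error(align_pair("", "AAAA"), "empty")
  expect_error(align_pair("AB1A", "AAAA"), "1")
  expect_error(align_pair("AAAA", "AAOA"), "O")
})

test_that("percent identity follows both conventions, with coverage", {
  expect_equal(percent_identity(align_pair("ACDE", "ACDE"))$identity, 1)
  expect_equal(percent_identity(align_pair("ACDE", "ACDF"))$identity, 0.75)
  pi <- percent_identity(align_pair("ACDEFG", "ACDE"))
  expect_equal(pi$identity, 1)                 # shorter-sequence denominator
  expect_equal(unname(pi$coverage["a"]), 4 / 6)
  expect_equal(unname(pi$coverage["b"]), 1)
  pc <- percent_identity(align_pair("ACDEFG", "ACDE"), convention = "columns")
  expect_equal(pc$identity, 1)                 # 4 of 4 aligned columns
})

test_that("consensus derivation handles uniform, tied and noisy columns", {
  m <- new_msa(c("s1", "s2", "s3"), c("A", "A", "A"))
  cp <- derive_consensus(m)
  expect_equal(cp$consensus, "A")
  expect_equal(cp$homogeneity, 1)
  # L,L,I,V: L and I tie at summed score 11; alphabetical tie-break -> I
  m2 <- new_msa(paste0("s", 1:4), c("L", "L", "I", "V"))
  expect_equal(derive_consensus(m2)$raw_consensus, "I")
  # a scattered column falls below the 0.5 mask threshold
  m3 <- new_msa(paste0("s", 1:4), c("A", "D", "K", "F"))
  cp3 <- derive_consensus(m3)
  expect_lt(cp3$homogeneity, 0.5)
  expect_equal(cp3$consensus, "x")
})

test_that("consensus matches brute-force argmax on random columns", {
  set.seed(11)
  B <- blosum62()
  for (i in 1:200) {
    col <- sample(AA, sample(2:12, 1), replace = TRUE)
    expect_equal(graspmine:::consensus_residue(col, B),
                 naive_consensus(col, B))
  }
})

test_that("homogeneity is invariant to row order and duplication", {
  set.seed(5)
  col <- sample(AA, 6, replace = TRUE)
  k <- graspmine:::consensus_residue(col)
  h1 <- graspmine:::column_homogeneity(col, k)
  expect_equal(graspmine:::column_homogeneity(sample(col), k), h1)
  expect_equal(graspmine:::column_homogeneity(rep(col, 3), k), h1)
})

test_that("all-gap columns yield '-' consensus and zero homogeneity", {
  m <- new_msa(c("a", "b"), c("A-C", "A-C"))
  cp <- derive_consensus(m)
  expect_equal(substr(cp$consensus, 2, 2), "-")
  expect_equal(cp$homogeneity[2], 0)
})

test_that("alignment filter drops gappy and low-homogeneity columns", {
  # column 2: 3 gaps of 5 rows (60%) -> removed; column 3 conserved -> kept
  rows <- c("AAC", "A-C", "A-C", "A-C", "AAC")
  m <- new_msa(paste0("s", 1:5), rows)
  f <- filter_alignment(m)
  expect_equal(attr(f, "kept_columns"), c(1L, 3L))
  # low homogeneity (G,L,H,V scatters to 0.096), no gaps -> removed
  m2 <- new_msa(paste0("s", 1:4), c("AG", "AL", "AH", "AV"))
  cp2 <- derive_consensus(m2)
  expect_lte(cp2$homogeneity[2], 0.1)
  f2 <- filter_alignment(m2, cp2)
  expect_true(all(cp2$homogeneity[attr(f2, "kept_columns")] > 0.1))
  expect_false(2L %in% attr(f2, "kept_columns"))
})

test_that("alignment filtering is idempotent and a column subsequence", {
  set.seed(9)
  rows <- vapply(1:6, function(i) {
    x <- sample(c(AA, "-"), 40, replace = TRUE, prob = c(rep(1, 20), 8))
    paste(x, collapse = "")
  }, "")
  m <- new_msa(paste0("s", 1:6), rows)
  f1 <- filter_alignment(m)
  expect_true(all(diff(attr(f1, "kept_columns")) > 0))
  f2 <- filter_alignment(f1)
  expect_equal(f2$rows, f1$rows)
})

test_that("a filter that removes everything warns instead of erroring", {
  m <- new_msa(c("a", "b", "c", "d"), c("GP", "LL", "HV", "VH"))
  expect_warning(f <- filter_alignment(m), "no columns")
  expect_true(attr(f, "empty"))
})

test_that("profile self-score equals the diagonal sum for a single sequence", {
  s <- "MKKLLT"
  sp <- scored_profile(new_msa("s1", s))
  expect_equal(profile_score(sp, s),
               sum(diag(blosum62())[strsplit(s, "")[[1]]]))
  # unrelated reversed sequence scores strictly less
  expect_lt(profile_score(sp, "WWDDNN"), profile_score(sp, s))
})

test_that("profile scoring matches an independent DP on small instances", {
  set.seed(13)
  for (i in 1:30) {
    seqs <- setNames(c(random_seq(8), random_seq(8)), c("a", "b"))
    m <- align_msa(seqs)
    sp <- scored_profile(m)
    s <- random_seq(sample(4:10, 1))
    expect_equal(profile_score(sp, s),
                 r_local_profile_score(sp$scores,
                                       match(strsplit(s, "")[[1]],
                                             colnames(sp$scores)),
                                       11, 1))
  }
})

test_that("profile scores its own consensus at least as high as random sequences", {
  set.seed(17)
  ok <- 0L
  for (i in 1:50) {
    seqs <- setNames(lapply(1:3, function(j) random_seq(25)),
                     paste0("s", 1:3))
    seqs <- unlist(seqs)
    m <- align_msa(seqs)
    cp <- derive_consensus(m)
    sp <- scored_profile(m)
    self <- profile_score(sp, consensus_sequence(cp))
    if (all(vapply(1:5, function(j)
      profile_score(sp, random_seq(25)) <= self, TRUE))) ok <- ok + 1L
  }
  expect_gte(ok, 48L)  # dominance on motif-free random profiles
})

test_that("substitution matrix loader is symmetric with positive diagonal", {
  B <- blosum62()
  expect_true(all(B == t(B)))
  expect_true(all(diag(unclass(B))[AA] > 0))
  expect_true(all(unclass(B)["X", ] == 0))   # unknowns score 0
})
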