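test_that("leader motif scanner finds constructed matches inside the window", {
  hits <- scan_leader_motif("MSTNPILEFARQ")
  expect_true(any(hits$start == 5 & hits$end == 9))   # P-I-L-E-F
  expect_equal(nrow(scan_leader_motif("MSTNAILEARQ")), 0L)  # no proline
  far <- paste0(paste(rep("K", 39), collapse = ""), "PILEF")
  expect_equal(nrow(scan_leader_motif(far, window = 30)), 0L)
  expect_gt(nrow(scan_leader_motif(far, window = 40)), 0L)
})

test_that("GG scanner enumerates doublets with and without the glycine rule", {
  s <- "MKKLLSAGGETT"
  all_hits <- scan_gg_motif(s)
  expect_equal(all_hits$start, c(6, 7, 8, 9))   # SA, AG, GG, GE
  gly <- scan_gg_motif(s, require_gly = TRUE)
  expect_equal(gly$start, c(7, 8, 9))           # AG, GG, GE
  expect_equal(nrow(scan_gg_motif("MKWLIRT")), 0L)
  # "SA" only counts when the glycine requirement is off
  expect_equal(nrow(scan_gg_motif("SA")), 1L)
  expect_equal(nrow(scan_gg_motif("SA", require_gly = TRUE)), 0L)
})

test_that("core patterns match fixed and variable-gap signatures", {
  h1 <- match_core_pattern("TAAAADAAATAKAPSDADD", "TxxxxDxxxTxKxPSDxD[DE]")
  expect_equal(nrow(h1), 1L)
  expect_equal(c(h1$start, h1$end), c(1L, 19L))
  h2 <- match_core_pattern("TAAATAAAAAADAD", "TxxxTx(6-10)Dx(1-4)D")
  expect_true(any(h2$start == 1 & h2$end == 14))  # gap lengths (6, 1)
  expect_equal(nrow(match_core_pattern("TAAAT", "TxxxTx(6-10)Dx(1-4)D")), 0L)
  expect_error(motif_pattern("Tx(3-1)D"), "min > max")
  expect_error(motif_pattern("T!D"), "!")
})

test_that("scanners agree with the regex oracle on random sequences", {
  set.seed(61)
  pats <- c("TxxxTxxDxxxxDD", "TxxxTx(6-10)Dx(1-4)D",
            "TxxxxDxxxTxKxPSDxD[DE]", "PFFARFL")
  for (pat in pats) {
    for (i in 1:150) {
      # bias the alphabet toward the motif letters so matches occur
      s <- paste(sample(c(AA, "T", "T", "D", "D", "A"), 40, TRUE),
                 collapse = "")
      expect_true(hits_equal(match_core_pattern(s, pat),
                             oracle_match_pattern(s, pat)),
                  info = paste(pat, s))
    }
  }
})

test_that("leader scanner agrees with an explicit oracle on random sequences", {
  set.seed(67)
  hset <- hydrophobic_set()
  for (i in 1:300) {
    s <- paste(sample(c(AA, "P", "P", "L", "I"), 45, TRUE), collapse = "")
    mine <- scan_leader_motif(s, window = 30)
    chars <- strsplit(s, "")[[1]]
    exp <- NULL
    for (st in seq_len(min(30, length(chars)))) {
      for (g in 1:2) {
        en <- st + 3 + g
        if (en > length(chars)) next
        w <- chars[st:en]
        if (w[1] == "P" && w[2] %in% hset && w[3] %in% hset &&
            w[length(w)] %in% hset) {
          exp <- rbind(exp, c(st, en))
        }
      }
    }
    if (is.null(exp)) {
      expect_equal(nrow(mine), 0L)
    } else {
      colnames(exp) <- c("start", "end")
      expect_true(hits_equal(mine, exp), info = s)
    }
  }
})

test_that("candidate filter applies the length-majority and rank rules", {
  membership <- setNames(c(1, 1, 1, 2, 2, 2, 3), paste0("p", 1:7))
  lens <- setNames(c(120, 130, 200, 160, 170, 140, 100), paste0("p", 1:7))
  rank <- setNames(c(1, 5, 6, 1, 1, 2, 3), paste0("p", 1:7))
  out <- candidate_filter(membership, lens, rank)
  expect_true(out$kept[out$cluster == 1])    # 2/3 short, member at rank 1
  expect_false(out$kept[out$cluster == 2])   # only 1/3 short
  expect_false(out$kept[out$cluster == 3])   # nearest anchor rank 3
})

test_that("candidate filter is monotone in adding a short near-anchor member", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    membership <- setNames(rep(1, n), paste0("p", 1:n))
    lens <- setNames(sample(50:250, n, TRUE), paste0("p", 1:n))
    rank <- setNames(sample(0:8, n, TRUE), paste0("p", 1:n))
    before <- candidate_filter(membership, lens, rank)$kept
    membership2 <- c(membership, pX = 1)
    lens2 <- c(lens, pX = 100)
    rank2 <- c(rank, pX = 1)
    after <- candidate_filter(membership2, lens2, rank2)$kept
    if (before) expect_true(after)
  }
})

test_that("classification status is a pure function of the evidence flags", {
  combos <- expand.grid(known_any = c(FALSE, TRUE),
                        passed = c(FALSE, TRUE),
                        doublet = c(FALSE, TRUE),
                        gg_leader = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    ev <- c(ref_overlap = cb$known_any, motif_match = FALSE,
            annotated = FALSE, passed_filter = cb$passed,
            conserved_doublet = cb$doublet, gg_leader_nterm = cb$gg_leader)
    got <- graspmine:::precursor_status(ev)
    want <- if (cb$known_any) "known"
            else if (cb$passed && cb$doublet) "new"
            else if (cb$gg_leader) "candidate"
            else "rejected"
    expect_equal(got, want, info = paste(unlist(cb), collapse = ","))
    # the three known routes are interchangeable
    ev2 <- ev; ev2[["ref_overlap"]] <- FALSE; ev2[["motif_match"]] <- cb$known_any
    expect_equal(graspmine:::precursor_status(ev2), want)
    ev3 <- ev; ev3[["ref_overlap"]] <- FALSE; ev3[["annotated"]] <- cb$known_any
    expect_equal(graspmine:::precursor_status(ev3), want)
  }
})

test_that("classification routes reference overlap, motifs and annotations", {
  set.seed(73)
  ref <- c(refA = random_seq(80))
  near <- setNames(mutate_seq(ref[[1]], 6), "m1")   # >90% identical
  prof <- derive_consensus(align_msa(near))
  call <- classify_precursor(near, prof, passed_filter = FALSE,
                             reference_seqs = ref, motif_library = NULL)
  expect_equal(call$status, "known")
  # a bundled-motif carrier is known without references
  carrier <- setNames(paste0(random_seq(20), "TAAATAADAAAADD",
                             random_seq(10)), "m2")
  prof2 <- derive_consensus(align_msa(carrier))
  call2 <- classify_precursor(carrier, prof2, passed_filter = FALSE)
  expect_equal(call2$status, "known")
  # annotation flag alone suffices
  anon <- setNames(random_seq(60), "m3")
  prof3 <- derive_consensus(align_msa(anon))
  call3 <- classify_precursor(anon, prof3, passed_filter = FALSE,
                              motif_library = NULL, annotations = "m3")
  expect_equal(call3$status, "known")
})

test_that("a conserved small doublet plus the filter yields status new", {
  set.seed(79)
  base <- paste0(random_seq(10), "GG", random_seq(30))
  seqs <- setNames(c(base, mutate_seq(base, 3), mutate_seq(base, 3)),
                   paste0("m", 1:3))
  # keep the doublet intact in all members
  seqs <- vapply(seqs, function(s) {
    substr(s, 11, 12) <- "GG"; s
  }, "")
  prof <- derive_consensus(align_msa(seqs))
  call <- classify_precursor(seqs, prof, passed_filter = TRUE,
                             motif_library = NULL)
  expect_equal(call$status, "new")
  expect_true(call$evidence[["conserved_doublet"]])
})

test_that("bond and thioether candidates map conserved core residues", {
  m <- new_msa(paste0("s", 1:3), rep("TAAAADAAD", 3))
  prof <- derive_consensus(m)
  bonds <- map_bond_residues(prof, core_region = c(1, 9))
  expect_equal(bonds$bond_candidates$position, c(1L, 6L, 9L))
  expect_equal(bonds$bond_candidates$residue, c("T", "D", "D"))
  m2 <- new_msa(paste0("s", 1:3), rep("ACA", 3))
  b2 <- map_bond_residues(derive_consensus(m2), core_region = c(1, 3))
  expect_equal(b2$thioether_candidates$position, 2L)
  # masked columns are never reported
  m3 <- new_msa(paste0("s", 1:4), c("TWKDA", "TCDKA", "TKWEA", "TDCSA"))
  p3 <- derive_consensus(m3)
  b3 <- map_bond_residues(p3, core_region = c(1, 5))
  expect_true(all(p3$homogeneity[b3$bond_candidates$position] >= 0.5))
})

test_that("planted precursors round-trip through every scanner", {
  set.seed(83)
  for (i in 1:10) {
    pat <- c("TxxxTxxDxxxxDD", "TxxxTx(6-10)Dx(1-4)D")[[(i %% 2) + 1]]
    p <- synth_precursor(pat)
    expect_lte(nchar(p$sequence), 150)
    lead <- scan_leader_motif(p$sequence)
    expect_true(any(lead$start == p$leader[["start"]] &
                    lead$end == p$leader[["end"]]))
    gg <- scan_gg_motif(p$sequence)
    expect_true(any(gg$start == p$gg[["start"]]))
    core <- match_core_pattern(p$sequence, pat)
    expect_true(any(core$start == p$core[["start"]] &
                    core$end == p$core[["end"]]))
  }
})

test_that("leader false-positive rate on random sequences matches theory", {
  # P(match at a fixed start) for P-h-h-x{1,2}-h with |h| = 9:
  # p1 = (1/20) * (9/20)^2 * q where q = P(h at +4 or +5) = 1 - (11/20)^2
  set.seed(89)
  n <- 2000
  hit <- 0L
  for (i in 1:n) {
    s <- random_seq(34)
    hit <- hit + (nrow(scan_leader_motif(s, window = 30)) > 0L)
  }
  # per-window probability via inclusion over 30 starts (independent
  # approximation checked against simulation, not asserted tightly)
  p_start <- (1 / 20) * (9 / 20)^2 * (1 - (11 / 20)^2)
  p_window <- 1 - (1 - p_start)^30
  se <- sqrt(p_window * (1 - p_window) / n)
  expect_lt(abs(hit / n - p_window), 4 * se + 0.01)
})
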