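# Independent oracles and small generators used across the suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len) paste(sample(AA, len, replace = TRUE),
                                  collapse = "")

mutate_seq <- function(s, k) {
  x <- strsplit(s, "")[[1]]
  i <- sample(length(x), k)
  x[i] <- sample(AA, k, replace = TRUE)
  paste(x, collapse = "")
}

# brute-force consensus: explicit double loop over the 20 residues
naive_consensus <- function(residues, mat) {
  best <- NULL
  best_sum <- -Inf
  for (k in AA) {
    ssum <- 0
    for (r in residues) ssum <- ssum + mat[k, r]
    if (ssum > best_sum) { best_sum <- ssum; best <- k }
  }
  best
}

# naive UPGMA via the defining property: the distance between two
# clusters is the arithmetic mean of all original pairwise distances
# between their members.  Returns the cophenetic matrix.
naive_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(members) > 1L) {
    k <- length(members)
    bi <- 0L; bj <- 0L; bd <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        d <- mean(D[members[[i]], members[[j]]])
        if (d < bd) { bd <- d; bi <- i; bj <- j }
      }
    }
    for (a in members[[bi]]) for (b in members[[bj]]) {
      coph[a, b] <- coph[b, a] <- bd
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  coph
}

# regex-based motif oracle: expand variable gaps into all fixed-length
# alternatives and try an anchored regex at every start position
oracle_match_pattern <- function(seq, pattern) {
  pattern <- gsub("–|—|‒", "-", pattern)
  tokens <- list()
  i <- 1L
  chars <- strsplit(pattern, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x" && i < length(chars) && chars[i + 1L] == "(") {
      close <- i + 1L
      while (chars[close] != ")") close <- close + 1L
      spec <- paste(chars[(i + 2L):(close - 1L)], collapse = "")
      nums <- as.integer(strsplit(spec, "[-,]")[[1]])
      if (length(nums) == 1L) nums <- c(nums, nums)
      tokens[[length(tokens) + 1L]] <- sprintf(".{%d}", seq(nums[1], nums[2]))
      i <- close + 1L
    } else if (ch == "x") {
      tokens[[length(tokens) + 1L]] <- "."
      i <- i + 1L
    } else if (ch == "[") {
      close <- i
      while (chars[close] != "]") close <- close + 1L
      tokens[[length(tokens) + 1L]] <-
        paste(chars[i:close], collapse = "")
      i <- close + 1L
    } else {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    }
  }
  regexes <- Reduce(function(acc, tk) {
    unlist(lapply(acc, function(a) paste0(a, tk)))
  }, tokens, accumulate = FALSE, init = "")
  hits <- NULL
  n <- nchar(seq)
  for (s in seq_len(n)) {
    sub <- substr(seq, s, n)
    for (re in regexes) {
      m <- regexpr(paste0("^", re), sub)
      if (m > 0) {
        hits <- rbind(hits, c(s, s + attr(m, "match.length") - 1L))
      }
    }
  }
  if (is.null(hits)) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  }
  hits <- unique(hits)
  colnames(hits) <- c("start", "end")
  hits[order(hits[, 1], -hits[, 2]), , drop = FALSE]
}

# independent plain-R Gotoh local DP for profile-to-sequence scoring
r_local_profile_score <- function(scores, idx, go, ge) {
  n <- nrow(scores); m <- length(idx)
  M <- matrix(-Inf, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      Ix[i, j] <- max(M[i - 1, j] - (go + ge), Ix[i - 1, j] - ge)
      Iy[i, j] <- max(M[i, j - 1] - (go + ge), Iy[i, j - 1] - ge)
      sc <- scores[i - 1, idx[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1],
                     0) + sc
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# 4x4 hit matrix equality helper
hits_equal <- function(df, m) {
  a <- unique(cbind(df$start, df$end))
  b <- unique(cbind(as.integer(m[, "start"]), as.integer(m[, "end"])))
  isTRUE(all.equal(a[order(a[, 1], a[, 2]), , drop = FALSE],
                   b[order(b[, 1], b[, 2]), , drop = FALSE]))
}
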