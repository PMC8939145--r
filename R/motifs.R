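#' Parse a motif pattern
#'
#' Pattern language used for leader/cleavage/core motifs: an uppercase
#' letter matches that residue; `[DE]` matches a residue class; `x`
#' matches any residue; `x(n-m)` (or `x(n,m)`, en dash accepted) matches
#' a variable gap of n to m arbitrary residues; `x(n)` a fixed gap.
#'
#' @param pattern pattern text, e.g. `"TxxxTx(6-10)Dx(1-4)D"`.
#' @param name optional motif name.
#' @param region one of `"leader"`, `"cleavage"`, `"core"`.
#' @return a `motif_pattern`: token list plus metadata.
#' @export
motif_pattern <- function(pattern, name = pattern,
                          region = c("core", "leader", "cleavage")) {
  region <- match.arg(region)
  chars <- strsplit(pattern, "")[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "x") {
      if (i < n && chars[i + 1L] == "(") {
        close <- i + 1L
        while (close <= n && chars[close] != ")") close <- close + 1L
        if (close > n) stop("unparseable pattern token: unterminated 'x(' in ",
                            dQuote(pattern, FALSE))
        spec <- paste(chars[(i + 2L):(close - 1L)], collapse = "")
        parts <- strsplit(spec, "[-–‒—,]")[[1]]
        nums <- suppressWarnings(as.integer(parts))
        if (anyNA(nums) || length(nums) < 1L || length(nums) > 2L) {
          stop("unparseable pattern token: 'x(", spec, ")'")
        }
        lo <- nums[1L]; hi <- if (length(nums) == 2L) nums[2L] else nums[1L]
        if (lo > hi) stop("unparseable pattern token: 'x(", spec,
                          ")' has min > max")
        tokens[[length(tokens) + 1L]] <- list(type = "gap", min = lo, max = hi)
        i <- close + 1L
      } else {
        tokens[[length(tokens) + 1L]] <- list(type = "gap", min = 1L, max = 1L)
        i <- i + 1L
      }
    } else if (ch == "[") {
      close <- i
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) stop("unparseable pattern token: unterminated '[' in ",
                          dQuote(pattern, FALSE))
      set <- chars[(i + 1L):(close - 1L)]
      if (length(set) == 0L || !all(set %in% AA20)) {
        stop("unparseable pattern token: '[",
             paste(set, collapse = ""), "]'")
      }
      tokens[[length(tokens) + 1L]] <- list(type = "class", set = set)
      i <- close + 1L
    } else if (ch %in% AA20) {
      tokens[[length(tokens) + 1L]] <- list(type = "class", set = ch)
      i <- i + 1L
    } else {
      stop("unparseable pattern token: ", dQuote(ch, FALSE), " in ",
           dQuote(pattern, FALSE))
    }
  }
  structure(list(pattern = pattern, name = name, region = region,
                 tokens = tokens),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("Motif '%s' (%s): %s\n", x$name, x$region, x$pattern))
  invisible(x)
}

# enumerate all matches of a token list in seq characters; returns
# matrix of (start, end); all alternative variable-gap spans explored
match_tokens <- function(chars, tokens, starts = seq_along(chars)) {
  n <- length(chars)
  hits_start <- integer(0); hits_end <- integer(0)
  recurse <- function(ti, pos, s0) {
    if (ti > length(tokens)) {
      hits_start <<- c(hits_start, s0)
      hits_end <<- c(hits_end, pos - 1L)
      return(invisible())
    }
    tk <- tokens[[ti]]
    if (tk$type == "class") {
      if (pos <= n && chars[pos] %in% tk$set) recurse(ti + 1L, pos + 1L, s0)
    } else {
      for (L in seq(tk$min, tk$max)) {
        if (pos + L - 1L <= n) recurse(ti + 1L, pos + L, s0)
      }
    }
  }
  for (s in starts) recurse(1L, s, s)
  if (length(hits_start) == 0L) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  }
  m <- unique(cbind(start = hits_start, end = hits_end))
  # leftmost-longest ordering
  m[order(m[, "start"], -m[, "end"]), , drop = FALSE]
}

#' Match a core pattern against a sequence
#'
#' Reports every match, including all alternative spans of variable
#' gaps; overlapping matches are kept, ordered leftmost-longest.
#'
#' @param seq protein sequence.
#' @param pattern a [motif_pattern] (or pattern text).
#' @return data.frame of `motif_hit`s: `start`, `end` (1-based
#'   inclusive), `name`, `match`.
#' @export
match_core_pattern <- function(seq, pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  chars <- strsplit(toupper(seq), "")[[1]]
  m <- match_tokens(chars, pattern$tokens)
  hits_df(chars, m, pattern$name)
}

hits_df <- function(chars, m, name) {
  data.frame(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
             name = rep(name, nrow(m)),
             match = vapply(seq_len(nrow(m)), function(i)
               paste(chars[m[i, "start"]:m[i, "end"]], collapse = ""), ""),
             stringsAsFactors = FALSE)
}

#' Default hydrophobic residue set
#'
#' The residues accepted for the `h` positions of the leader motif.
#' @return character vector.
#' @export
hydrophobic_set <- function() c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Default small-residue set for GG-like doublets
#'
#' @return character vector (Gly, Ala, Ser, Cys, Glu).
#' @export
small_residue_set <- function() c("G", "A", "S", "C", "E")

#' Scan for the leader motif Phhx(1,2)h
#'
#' Finds the leader signature — proline, two hydrophobic residues, one
#' or two arbitrary residues, a hydrophobic residue — whose start lies
#' within the N-terminal window where leader peptides carry their
#' conserved block.
#'
#' @param seq protein sequence.
#' @param window N-terminal window for the match start (default 30).
#' @param hydrophobic residues accepted for `h`.
#' @param gap_range length-2 integer range for the variable gap.
#' @return data.frame of hits (see [match_core_pattern()]).
#' @export
scan_leader_motif <- function(seq, window = 30,
                              hydrophobic = hydrophobic_set(),
                              gap_range = c(1L, 2L)) {
  tokens <- list(list(type = "class", set = "P"),
                 list(type = "class", set = hydrophobic),
                 list(type = "class", set = hydrophobic),
                 list(type = "gap", min = gap_range[1L], max = gap_range[2L]),
                 list(type = "class", set = hydrophobic))
  chars <- strsplit(toupper(seq), "")[[1]]
  starts <- seq_len(min(window, length(chars)))
  m <- match_tokens(chars, tokens, starts = starts)
  hits_df(chars, m, "Phhx(1,2)h")
}

#' Scan for small-residue (GG-like) cleavage doublets
#'
#' Reports adjacent doublets drawn from the small-residue set within a
#' region; with `require_gly` at least one of the two must be glycine.
#' Hits are reported N- to C-terminal.
#'
#' @param seq protein sequence.
#' @param small_set residues counted as small (default G, A, S, C, E).
#' @param require_gly require at least one G in the doublet.
#' @param region optional `c(from, to)` positions restricting the
#'   doublet to lie fully inside.
#' @return data.frame of hits.
#' @export
scan_gg_motif <- function(seq, small_set = small_residue_set(),
                          require_gly = FALSE, region = NULL) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (is.null(region)) region <- c(1L, n)
  stopifnot(region[1L] >= 1L, region[2L] <= n)
  starts <- integer(0)
  if (region[2L] > region[1L] - 1L) {
    for (i in seq(region[1L], max(region[1L], region[2L] - 1L))) {
      if (i + 1L > region[2L]) next
      ok <- chars[i] %in% small_set && chars[i + 1L] %in% small_set
      if (ok && require_gly) ok <- "G" %in% chars[c(i, i + 1L)]
      if (ok) starts <- c(starts, i)
    }
  }
  m <- cbind(start = starts, end = starts + 1L)
  if (length(starts) == 0L) {
    m <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  }
  hits_df(chars, m, "GG")
}

#' Read a motif library
#'
#' One pattern per line: `name<TAB>region<TAB>pattern`.
#'
#' @param path pattern file.
#' @return list of [motif_pattern] objects.
#' @export
read_motif_library <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("name", "region", "pattern"),
                   stringsAsFactors = FALSE, comment.char = "#")
  lapply(seq_len(nrow(df)), function(i)
    motif_pattern(df$pattern[i], name = df$name[i], region = df$region[i]))
}

#' The bundled graspetide motif library
#'
#' The core and leader signatures bundled with the package: the
#' microviridin leader block PFFARFL, the Salinispora-type core
#' TxxxTxxDxxxxDD, the CPR branch core TxxxTx(6-10)Dx(1-4)D and the
#' chryseoviridin core TxxxxDxxxTxKxPSDxD[DE]. Additional reference
#' motifs can be supplied via [read_motif_library()].
#'
#' @return list of [motif_pattern] objects.
#' @export
graspetide_motifs <- function() {
  path <- system.file("extdata", "graspetide_motifs.tsv",
                      package = "graspmine")
  read_motif_library(path)
}

#' Match a sequence against a motif library
#'
#' @param seq protein sequence.
#' @param library list of [motif_pattern]s.
#' @return data.frame of hits across all patterns.
#' @export
match_motif_library <- function(seq, library = graspetide_motifs()) {
  do.call(rbind, lapply(library, function(p) match_core_pattern(seq, p)))
}
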