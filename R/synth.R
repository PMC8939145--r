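# sample() that never auto-expands a length-1 vector into 1:n
resample <- function(x, size = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Specification of a planted protein family
#'
#' @param family_id family label.
#' @param root_length length of the (uniform random) root sequence.
#' @param rate per-site substitution probability per tree branch, in
#'   `[0, 1)`.
#' @param n_members number of leaves to generate.
#' @param role one of `anchor`, `precursor`, `ancillary`, `decoy`.
#' @return a `family_spec` list.
#' @export
family_spec <- function(family_id, root_length, rate, n_members,
                        role = c("anchor", "precursor", "ancillary",
                                 "decoy")) {
  role <- match.arg(role)
  if (rate < 0 || rate >= 1) stop("substitution rate must be in [0, 1)")
  stopifnot(n_members >= 1L, root_length >= 1L)
  structure(list(family_id = family_id, root_length = root_length,
                 rate = rate, n_members = n_members, role = role),
            class = "family_spec")
}

#' Evolve a protein family from a random root
#'
#' The root is drawn i.i.d. uniform over the 20 residues; members are
#' produced along a random bifurcating tree, each branch substituting
#' every site independently with the spec's rate. A substituted residue
#' is replaced by another residue with probability proportional to
#' `exp(score/2)` under the substitution matrix, which keeps
#' within-family alignability at moderate rates the way real protein
#' families diverge.
#'
#' @param spec a [family_spec].
#' @param seed optional integer; when given, seeds the RNG (omit to use
#'   the ambient RNG state, e.g. inside [generate_locus_set()]).
#' @param matrix substitution matrix for the replacement weights.
#' @return named character vector of member sequences
#'   (`<family>_<k>`), with the root attached as attribute `root`.
#' @export
evolve_family <- function(spec, seed = NULL, matrix = blosum62()) {
  stopifnot(inherits(spec, "family_spec"))
  if (!is.null(seed)) set.seed(seed)
  W <- exp(unclass(matrix)[AA20, AA20] / 2)
  diag(W) <- 0
  root <- sample(AA20, spec$root_length, replace = TRUE)
  mutate <- function(s) {
    hit <- which(runif(length(s)) < spec$rate)
    for (i in hit) s[i] <- resample(AA20, 1L, prob = W[s[i], ])
    s
  }
  evolve <- function(s, k) {
    if (k == 1L) return(list(mutate(s)))
    kl <- resample(seq_len(k - 1L), 1L)
    c(evolve(mutate(s), kl), evolve(mutate(s), k - kl))
  }
  leaves <- evolve(root, spec$n_members)
  seqs <- vapply(leaves, paste, "", collapse = "")
  names(seqs) <- sprintf("%s_%02d", spec$family_id, seq_along(seqs))
  attr(seqs, "root") <- paste(root, collapse = "")
  seqs
}

#' Generate one synthetic precursor sequence
#'
#' Emulates the leader/cleavage/core architecture of a graspetide
#' precursor: a random leader carrying one planted Phhx(1,2)h occurrence
#' whose start lies within `leader_window`, a GG-like small-residue
#' doublet (always containing one glycine), a core instantiating
#' `core_pattern` (class tokens choose a member, wildcards and variable
#' gaps drawn at random), and a short random tail. All planted
#' coordinates are recorded.
#'
#' @param core_pattern a [motif_pattern] or pattern text.
#' @param leader_window N-terminal window the leader motif must start in.
#' @param max_len total length budget in residues (default 150).
#' @param seed optional RNG seed (omit to use the ambient RNG state).
#' @param hydrophobic,small_set residue sets for the planted motifs.
#' @return list with `sequence` and 1-based inclusive coordinate pairs
#'   `leader`, `gg`, `core`.
#' @export
synth_precursor <- function(core_pattern, leader_window = 30, max_len = 150,
                            seed = NULL, hydrophobic = hydrophobic_set(),
                            small_set = small_residue_set()) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(core_pattern, "motif_pattern")) {
    core_pattern <- motif_pattern(core_pattern)
  }
  # instantiate the core
  core <- character(0)
  for (tk in core_pattern$tokens) {
    if (tk$type == "class") {
      core <- c(core, resample(tk$set, 1L))
    } else {
      L <- resample(seq(tk$min, tk$max), 1L)
      core <- c(core, sample(AA20, L, replace = TRUE))
    }
  }
  # leader: Met start, random residues, planted P-h-h-x{1,2}-h
  lead_len <- resample(14:22, 1L)
  gap <- resample(1:2, 1L)
  motif_len <- 4L + gap
  mstart_max <- min(leader_window, lead_len - motif_len + 1L)
  if (mstart_max < 2L) stop("infeasible length budget for the leader window")
  mstart <- resample(seq(2L, mstart_max), 1L)
  leader <- c("M", sample(AA20, lead_len - 1L, replace = TRUE))
  motif <- c("P", resample(hydrophobic, 1L), resample(hydrophobic, 1L),
             sample(AA20, gap, replace = TRUE), resample(hydrophobic, 1L))
  leader[seq(mstart, mstart + motif_len - 1L)] <- motif
  # GG-like cleavage doublet: one glycine plus one small residue
  doublet <- resample(list(c("G", "G"), c("G", resample(setdiff(small_set, "G"), 1L)),
                           c(resample(setdiff(small_set, "G"), 1L), "G")), 1L)[[1]]
  tail_len <- resample(0:8, 1L)
  total <- lead_len + 2L + length(core) + tail_len
  if (lead_len + 2L + length(core) > max_len) {
    stop("infeasible length budget: leader + doublet + core exceed max_len")
  }
  if (total > max_len) { tail_len <- max_len - (lead_len + 2L + length(core)) }
  tail_res <- if (tail_len > 0L) sample(AA20, tail_len, replace = TRUE) else
    character(0)
  seq <- c(leader, doublet, core, tail_res)
  list(sequence = paste(seq, collapse = ""),
       leader = c(start = mstart, end = mstart + motif_len - 1L),
       gg = c(start = lead_len + 1L, end = lead_len + 2L),
       core = c(start = lead_len + 3L, end = lead_len + 2L + length(core)))
}

# default study conditions -------------------------------------------------

#' Default anchor branch specifications
#'
#' Three divergent ATP-grasp-like anchor branches (the member counts are
#' filled in by [generate_locus_set()] from the locus assignment).
#' @return list of [family_spec]s.
#' @export
default_anchor_specs <- function() {
  list(family_spec("ATPG1", 300, 0.04, 1, "anchor"),
       family_spec("ATPG2", 320, 0.04, 1, "anchor"),
       family_spec("ATPG3", 280, 0.04, 1, "anchor"))
}

#' Default precursor family definitions
#'
#' Six precursor families, two per anchor branch: three instantiate
#' cores from the bundled motif library (so they classify as "known")
#' and three carry novel core patterns absent from the library.
#' @return data.frame: `family_id`, `branch`, `pattern`, `known`.
#' @export
default_precursor_patterns <- function() {
  data.frame(
    family_id = c("PREK1", "PREK2", "PREK3", "PREN1", "PREN2", "PREN3"),
    branch = c(1L, 2L, 3L, 1L, 2L, 3L),
    pattern = c("TxxxTxxDxxxxDD",            # bundled (Salinispora-type)
                "TxxxTx(6-10)Dx(1-4)D",      # bundled (CPR branch)
                "TxxxxDxxxTxKxPSDxD[DE]",    # bundled (chryseoviridin)
                "SxxDxxxxKxxSxxE",           # novel cores
                "TxCxxxxDxxKxxD",
                "ExxxSxxxxTxxKD"),
    known = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Default ancillary family co-occurrence probabilities
#'
#' Probabilities with which each (long, non-precursor) ancillary family
#' joins the anchor directon of a locus, loosely graded like the
#' frequently-associated families around graspetide loci (peptidase and
#' transporter common, regulator rare).
#' @return named numeric vector.
#' @export
default_ancillary_probs <- function() {
  c(DGPEPT = 0.6, ABCTRAN = 0.4, SPASM = 0.3, OMETHYL = 0.15, REGUL = 0.05)
}

#' Generate a synthetic set of anchor loci
#'
#' Builds `n_loci` gene neighborhoods, each on its own contig: one
#' anchor gene (three divergent anchor branches by default), one or two
#' precursor genes at neighbor ranks within 2 of the anchor, ancillary
#' families joining the anchor directon independently with their
#' configured probabilities, and decoy genes at outer ranks separated by
#' strand flips or large gaps. A fraction of loci are near-copies
#' (every protein re-evolved at 1% per-site rate from a template locus,
#' anchor identity around 99%) to exercise redundancy weighting; the
#' first locus places its anchor at the contig edge. Output is fully
#' deterministic given `seed`.
#'
#' @param n_loci number of loci (default 50).
#' @param anchor_specs list of anchor [family_spec]s
#'   ([default_anchor_specs()]).
#' @param precursor_patterns data.frame as
#'   [default_precursor_patterns()].
#' @param ancillary_probs named co-occurrence probabilities
#'   ([default_ancillary_probs()]).
#' @param redundancy_fraction fraction of loci generated as near-copies
#'   (default 0.2).
#' @param precursor_rate substitution rate applied to the unconstrained
#'   positions of precursor family members (default 0.08).
#' @param seed RNG seed (default 1).
#' @return a `locus_set`: list with `proteins` (named character),
#'   `features` (`gene_features`), `anchor_ids`, and `truth` (gene
#'   family labels and roles, planted motif coordinates, locus
#'   redundancy groups, the ancillary probabilities and parameters).
#' @export
generate_locus_set <- function(n_loci = 50,
                               anchor_specs = default_anchor_specs(),
                               precursor_patterns = default_precursor_patterns(),
                               ancillary_probs = default_ancillary_probs(),
                               redundancy_fraction = 0.2,
                               precursor_rate = 0.08,
                               seed = 1) {
  stopifnot(n_loci >= 1L, all(ancillary_probs >= 0), all(ancillary_probs <= 1),
            redundancy_fraction >= 0, redundancy_fraction < 1)
  set.seed(seed)
  n_branch <- length(anchor_specs)
  n_red <- round(redundancy_fraction * n_loci)
  n_ind <- n_loci - n_red
  if (n_ind < 1L) stop("redundancy_fraction leaves no independent loci")
  branch_of <- (seq_len(n_ind) - 1L) %% n_branch + 1L

  # decide per-locus precursor composition first, then evolve the pools
  prec_by_branch <- split(seq_len(nrow(precursor_patterns)),
                          precursor_patterns$branch)
  locus_prec <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    fams <- prec_by_branch[[as.character(branch_of[i])]]
    k <- resample(c(1L, 1L, 1L, 2L), 1L)
    locus_prec[[i]] <- resample(fams, min(k, length(fams)))
  }
  prec_counts <- table(factor(unlist(locus_prec),
                              levels = seq_len(nrow(precursor_patterns))))
  # every family appears at least once among the independent loci
  for (f in which(prec_counts == 0)) {
    tgt <- which(branch_of == precursor_patterns$branch[f])[1L]
    locus_prec[[tgt]] <- unique(c(locus_prec[[tgt]], f))
  }
  prec_counts <- table(factor(unlist(locus_prec),
                              levels = seq_len(nrow(precursor_patterns))))

  # anchor pools
  anchor_pool <- vector("list", n_branch)
  for (b in seq_len(n_branch)) {
    spec <- anchor_specs[[b]]
    spec$n_members <- max(1L, sum(branch_of == b))
    anchor_pool[[b]] <- evolve_family(spec, matrix = blosum62())
  }

  # precursor pools: family root from synth_precursor, members mutate
  # only outside the planted leader/doublet/core spans
  prec_pool <- vector("list", nrow(precursor_patterns))
  prec_truth <- vector("list", nrow(precursor_patterns))
  W <- exp(unclass(blosum62())[AA20, AA20] / 2); diag(W) <- 0
  lib <- graspetide_motifs()
  for (f in seq_len(nrow(precursor_patterns))) {
    novel <- !precursor_patterns$known[f]
    # a family planted as novel must really be novel: reject draws that
    # chance-contain a library motif, so the ground-truth label holds
    is_novel_ok <- function(s) !novel || nrow(match_motif_library(s, lib)) == 0L
    for (try in 1:100) {
      root <- synth_precursor(precursor_patterns$pattern[f])
      if (is_novel_ok(root$sequence)) break
    }
    chars <- strsplit(root$sequence, "")[[1]]
    protected <- c(seq(root$leader["start"], root$leader["end"]),
                   seq(root$gg["start"], root$gg["end"]),
                   seq(root$core["start"], root$core["end"]))
    free <- setdiff(seq_along(chars), protected)
    nmem <- max(1L, as.integer(prec_counts[f]))
    mem <- character(nmem)
    for (k in seq_len(nmem)) {
      for (try in 1:100) {
        s <- chars
        hit <- free[runif(length(free)) < precursor_rate]
        for (i in hit) s[i] <- resample(AA20, 1L, prob = W[s[i], ])
        if (is_novel_ok(paste(s, collapse = ""))) break
      }
      mem[k] <- paste(s, collapse = "")
    }
    names(mem) <- sprintf("%s_%02d", precursor_patterns$family_id[f],
                          seq_len(nmem))
    prec_pool[[f]] <- mem
    prec_truth[[f]] <- root
  }

  # ancillary pools (long proteins, so the precursor length rule
  # rejects them) and decoy pools (short decoys sit at outer ranks)
  anc_ids <- names(ancillary_probs)
  anc_present <- matrix(runif(n_ind * length(anc_ids)) <
                          rep(ancillary_probs, each = n_ind),
                        n_ind, length(anc_ids),
                        dimnames = list(NULL, anc_ids))
  anc_pool <- lapply(seq_along(anc_ids), function(a) {
    spec <- family_spec(anc_ids[a], resample(180:260, 1L), 0.05,
                        max(1L, sum(anc_present[, a])), "ancillary")
    evolve_family(spec, matrix = blosum62())
  })
  names(anc_pool) <- anc_ids
  decoy_specs <- list(family_spec("DECS1", 95, 0.05, n_ind, "decoy"),
                      family_spec("DECS2", 210, 0.05, n_ind, "decoy"),
                      family_spec("DECL1", 240, 0.05, n_ind, "decoy"))
  decoy_pool <- lapply(decoy_specs, evolve_family, matrix = blosum62())

  used <- new.env(parent = emptyenv())  # per-pool cursors
  take <- function(pool_name, pool) {
    k <- (get0(pool_name, envir = used, ifnotfound = 0L)) + 1L
    assign(pool_name, k, envir = used)
    pool[((k - 1L) %% length(pool)) + 1L]
  }

  # assemble independent loci
  build_locus <- function(i) {
    b <- branch_of[i]
    anchor_seq <- take(paste0("A", b), anchor_pool[[b]])
    prec <- lapply(locus_prec[[i]], function(f)
      take(paste0("P", f), prec_pool[[f]]))
    prec_fams <- precursor_patterns$family_id[locus_prec[[i]]]
    ancs <- anc_ids[anc_present[i, ]]
    anc_seqs <- lapply(ancs, function(a) take(paste0("X", a), anc_pool[[a]]))
    # directon gene order: ancillaries, precursors, ANCHOR, ancillary tail
    n_anc_up <- if (length(ancs) > 1L) length(ancs) - 1L else length(ancs)
    genes <- list()
    add <- function(seq, fam, role, strand, gap) {
      genes[[length(genes) + 1L]] <<- list(seq = seq, fam = fam, role = role,
                                           strand = strand, gap = gap)
    }
    edge_locus <- (i == 1L)
    if (!edge_locus) {
      # upstream decoys, split off by strand flip / large gap
      add(take("D1", decoy_pool[[1L]]), "DECS1", "decoy", "-", 250L)
      if (runif(1) < 0.7) add(take("D3", decoy_pool[[3L]]), "DECL1", "decoy",
                              "-", resample(30:80, 1L))
      if (n_anc_up > 0L) for (a in seq_len(n_anc_up)) {
        add(anc_seqs[[a]], ancs[a], "ancillary", "+",
            if (a == 1L) 400L else resample(20:80, 1L))
      }
      for (k in seq_along(prec)) {
        add(prec[[k]], prec_fams[k], "precursor", "+",
            if (k == 1L && n_anc_up == 0L) 400L else resample(20:80, 1L))
      }
      add(anchor_seq, anchor_specs[[b]]$family_id, "anchor", "+",
          resample(20:80, 1L))
    } else {
      # anchor first on the contig
      add(anchor_seq, anchor_specs[[b]]$family_id, "anchor", "+", 0L)
      for (k in seq_along(prec)) {
        add(prec[[k]], prec_fams[k], "precursor", "+",
            resample(20:80, 1L))
      }
      if (n_anc_up > 0L) for (a in seq_len(n_anc_up)) {
        add(anc_seqs[[a]], ancs[a], "ancillary", "+",
            resample(20:80, 1L))
      }
    }
    if (length(ancs) > n_anc_up) {
      add(anc_seqs[[length(ancs)]], ancs[length(ancs)], "ancillary",
          "+", resample(20:80, 1L))
    }
    # downstream decoy beyond the directon
    add(take("D2", decoy_pool[[2L]]), "DECS2", "decoy", "+", 300L)
    genes
  }

  loci <- lapply(seq_len(n_ind), build_locus)
  redundancy_group <- seq_len(n_ind)

  # redundant loci: re-evolve every protein of a template at 1% rate;
  # planted motif spans of precursor genes stay untouched so the
  # ground-truth coordinates remain exact for every near-copy
  if (n_red > 0L) {
    mutate_seq <- function(s, keep = integer(0), rate = 0.01) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(runif(length(ch)) < rate & ch %in% AA20)
      hit <- setdiff(hit, keep)
      for (ii in hit) ch[ii] <- resample(AA20, 1L, prob = W[ch[ii], ])
      paste(ch, collapse = "")
    }
    novel_fams <- precursor_patterns$family_id[!precursor_patterns$known]
    protected_of <- function(fam) {
      f <- match(fam, precursor_patterns$family_id)
      if (is.na(f)) return(integer(0))
      tr <- prec_truth[[f]]
      c(seq(tr$leader[["start"]], tr$leader[["end"]]),
        seq(tr$gg[["start"]], tr$gg[["end"]]),
        seq(tr$core[["start"]], tr$core[["end"]]))
    }
    for (r in seq_len(n_red)) {
      tmpl <- ((r - 1L) %% n_ind) + 1L
      copy <- lapply(loci[[tmpl]], function(g) {
        g2 <- g
        keep <- if (g$role == "precursor") protected_of(g$fam) else integer(0)
        s2 <- mutate_seq(g$seq[[1L]], keep)
        if (g$fam %in% novel_fams) {
          # near-copies of novel precursors must stay library-motif free
          for (try in 1:100) {
            if (nrow(match_motif_library(s2, lib)) == 0L) break
            s2 <- mutate_seq(g$seq[[1L]], keep)
          }
        }
        g2$seq <- setNames(s2, paste0(names(g$seq), "r", r))
        g2
      })
      loci[[n_ind + r]] <- copy
      redundancy_group[n_ind + r] <- tmpl
    }
  }

  # lay out coordinates, collect tables
  proteins <- character(0)
  feat <- list()
  gene_rows <- list()
  motif_rows <- list()
  anchor_ids <- character(0)
  for (i in seq_along(loci)) {
    contig <- sprintf("ctg%03d", i)
    pos <- 1L
    for (k in seq_along(loci[[i]])) {
      g <- loci[[i]][[k]]
      gid <- sprintf("L%03d_g%02d", i, k)
      aa_len <- nchar(g$seq[[1L]])
      start <- pos + g$gap
      end <- start + 3L * aa_len + 2L
      pos <- end
      proteins[gid] <- unname(g$seq[[1L]])
      feat[[length(feat) + 1L]] <- data.frame(
        contig = contig, gene_id = gid, start = start, end = end,
        strand = g$strand, protein_id = gid, stringsAsFactors = FALSE)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        locus_id = i, gene_id = gid, family = g$fam, role = g$role,
        source_id = names(g$seq), stringsAsFactors = FALSE)
      if (g$role == "anchor") anchor_ids <- c(anchor_ids, gid)
      if (g$role == "precursor") {
        f <- match(g$fam, precursor_patterns$family_id)
        tr <- prec_truth[[f]]
        motif_rows[[length(motif_rows) + 1L]] <- data.frame(
          gene_id = gid, family = g$fam,
          leader_start = tr$leader[["start"]], leader_end = tr$leader[["end"]],
          gg_start = tr$gg[["start"]], gg_end = tr$gg[["end"]],
          core_start = tr$core[["start"]], core_end = tr$core[["end"]],
          pattern = precursor_patterns$pattern[f],
          known = precursor_patterns$known[f], stringsAsFactors = FALSE)
      }
    }
  }
  features <- validate_features(do.call(rbind, feat))
  truth <- list(genes = do.call(rbind, gene_rows),
                motifs = if (length(motif_rows)) do.call(rbind, motif_rows)
                         else NULL,
                redundancy = data.frame(locus_id = seq_along(loci),
                                        group = redundancy_group),
                ancillary_probs = ancillary_probs,
                params = list(n_loci = n_loci, n_independent = n_ind,
                              redundancy_fraction = redundancy_fraction,
                              precursor_rate = precursor_rate, seed = seed))
  structure(list(proteins = proteins, features = features,
                 anchor_ids = anchor_ids, truth = truth),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Synthetic locus set: %d loci, %d genes, %d anchors\n",
              max(x$truth$genes$locus_id), nrow(x$features),
              length(x$anchor_ids)))
  invisible(x)
}

#' Write a synthetic locus set to disk
#'
#' Emits the protein FASTA, the 6-column feature TSV, a GFF3 rendering,
#' the ground-truth gene table, and a YAML run manifest recording the
#' generator parameters and seed.
#'
#' @param x a `locus_set` from [generate_locus_set()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_locus_set <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(x$proteins, file.path(dir, "proteins.faa"))
  write_features(x$features, file.path(dir, "features.tsv"))
  write_gff3(x$features, file.path(dir, "features.gff3"))
  write.table(x$truth$genes, file.path(dir, "truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(x$truth$motifs)) {
    write.table(x$truth$motifs, file.path(dir, "truth_motifs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(yaml::as.yaml(list(generator = "generate_locus_set",
                                params = x$truth$params,
                                anchors = x$anchor_ids)),
             file.path(dir, "manifest.yaml"))
  invisible(dir)
}
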