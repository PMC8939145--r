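Package: graspmine
Title: Comparative Genomic Mining of Graspetide Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anchor-gene neighborhood analysis for graspetide (ATP-grasp
    ligase associated RiPP) biosynthetic gene clusters. Provides sequence
    scoring primitives (affine-gap pairwise and profile-to-sequence
    alignment under BLOSUM62, consensus derivation with per-column
    homogeneity, alignment filtering), a two-tier greedy identity
    clustering of locus proteins followed by consensus cross-scoring, a
    log-ratio score-to-distance transform, UPGMA tree construction and
    depth-cutoff dissection into homolog clusters, rule-based precursor
    peptide prediction from leader (Phhx(1,2)h), small-residue doublet
    (GG-like) and core motifs with known/new/candidate classification,
    redundancy-weighted gene-neighborhood (directon) association
    statistics, and a seeded synthetic locus generator used as the test
    substrate for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
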