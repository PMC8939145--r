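---
title: "Mining graspetide biosynthetic gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining graspetide biosynthetic gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspmine)
```

## The problem

Graspetides are ribosomally synthesized and post-translationally modified
peptides (RiPPs) whose macrocyclic lactone and lactam linkages are
installed by ATP-grasp ligases. Because the precursor peptides are short,
fast-evolving and often unannotated, the productive way to find them is
comparative genomics around the enzyme: locate ATP-grasp anchor genes,
collect their gene neighborhoods, cluster all neighborhood proteins into
homolog families with a sensitive profile-based procedure, and then apply
rule-based screens — precursor-sized proteins encoded right next to the
anchor, a hydrophobic leader signature, a small-residue (GG-like)
cleavage doublet, and conserved Ser/Thr/Asp/Glu/Lys residues that can
form the macrocycle bonds. Families co-occurring with the anchor in the
same directon (a run of closely spaced, co-oriented genes, used as an
operon proxy) point at ancillary biosynthesis, transport and regulation
genes.

`graspmine` implements this entire procedure as composable, deterministic
R functions, together with a seeded synthetic-locus generator that serves
as its test substrate.

## Sequence scoring primitives

All scoring uses BLOSUM62 with affine gap penalties (open 11, extend 1, a
gap of length $L$ costing $11 + L$). The pairwise aligner (`align_pair`)
is an internal Gotoh dynamic program, global or local, with a
deterministic traceback (diagonal over up over left); its scores agree
with `Biostrings::pairwiseAlignment` under the same parameters, which the
test suite verifies on random pairs. Unknown residues are mapped to `X`
and score 0 against everything.

Cluster members are aligned with a deterministic center-star progressive
scheme (`align_msa`): the longest member is the center, every other
member is globally aligned to it, and gap patterns are merged
("once a gap, always a gap"). This replaces an external multiple aligner
at the scale this package targets; `new_msa()` accepts any externally
computed alignment where higher quality is needed.

### Consensus and homogeneity

For each alignment column the consensus residue maximizes the sum of
BLOSUM62 scores against all non-gap residues of the column (ties broken
alphabetically). Column conservation ("homogeneity") is

$$H = \mathrm{clip}\left(\frac{\bar S - S_{rand}}{S_{self} - S_{rand}},\ 0,\ 1\right)$$

where $\bar S$ is the mean score of the consensus residue against the
column, $S_{self}$ its self-score and $S_{rand}$ its mean score against
the uniform residue distribution. This normalization yields 1 for a
uniform column, about 0 for a random one, and is monotone in
conservation, which makes the two fixed thresholds meaningful: columns
with $H < 0.5$ are masked to `x` in the consensus, and pre-phylogeny
filtering retains columns with under 50% gaps and $H > 0.1$. The formula
is isolated in one function (`column_homogeneity`) so an alternative
normalization can be swapped in.

## Homolog clustering

`cluster_homologs` composes the full procedure:

1. **Tier 1**: greedy centroid clustering at 0.9 identity collapses
   near-redundant sequences. Sequences are processed by decreasing
   length (ties by id), each joining the first centroid it matches.
   Identity here is measured over *all* columns of the global alignment,
   terminal gaps included — the semantics of greedy identity clusterers.
   The shorter-sequence convention would let a 35-residue precursor
   chance-match half its length inside a 300-residue enzyme, which is
   exactly the artifact this choice avoids. The loop carries two
   deterministic accelerations (a 4-mer prescreen and a diagonal
   shortcut for ≥95%-identical equal-length pairs); `accel = FALSE`
   forces the full dynamic program, and the suite checks both paths
   agree on evolved families.
2. **Tier 2**: the tier-1 representatives are clustered again at 0.5.
3. Each tier-2 cluster is aligned, a consensus derived, and a
   position-specific profile built (per-column mean substitution scores).
4. **Cross-scoring**: cluster A's profile is locally aligned to cluster
   B's consensus in both directions; self-scores score each profile
   against its own consensus. All scores are floored at 1.
5. **Distances**: $d_{AB} = -\ln(\max(s_{AB}, s_{BA}) /
   \min(s_{AA}, s_{BB}))$, clamped at 0.
6. **UPGMA** over the cluster distance matrix (merge height $d/2$,
   size-weighted means, lexicographic tie-break), then **dissection** at
   a height cutoff of $-\ln(0.01)/2 \approx 2.30$ — the height at which
   a pair's best cross-score is 1% of the smaller self-score. Every
   maximal subtree under the cutoff becomes one final cluster of
   homologs.

### The cross-score significance gate

A raw local alignment always returns *some* score, but profile searches
report nothing for non-significant pairs, and the procedure depends on
that sparsity: chance profile-vs-consensus scores run at 3–6% of a
typical self-score, which would place every unrelated pair below the
dissection height and collapse the tree. `cluster_homologs` therefore
gates cross-scores by their Karlin–Altschul expect value under the
standard gapped BLOSUM62 constants ($\lambda = 0.267$, $K = 0.041$):
scores with $E > 10^{-6}$ (the usual profile-search inclusion threshold)
are treated as "no hit" and floored. At this setting, chance scores
(about 35–50) fall well below the gate (about 82 for typical lengths)
while genuine homolog cross-scores (150–650 between tier-2 fragments of
one family) pass comfortably. The gate is a model of search-tool
reporting, not of full search statistics; `evalue_max = Inf` disables
it.

Whether profile scores are used raw or rescaled largely cancels in the
distance ratio; the implementation uses raw matrix-unit scores.

## Precursor screening

`candidate_filter` keeps clusters where strictly more than half the
members are ≤150 residues *and* at least one member lies within two
genes of an anchor. `classify_precursor` then applies a fixed decision
table, cluster-wide:

* **known** — any member joins a reference precursor under 50%
  identity / 50% coverage single linkage, or perfectly matches a library
  motif, or carries a precursor annotation;
* else **new** — the cluster passed the candidate filter and its
  alignment shows a conserved small-residue doublet (two adjacent
  columns, each with $H \ge 0.5$ and consensus in {G, A, S, C, E});
* else **candidate** — some member carries both a GG-like doublet and
  the leader motif within the N-terminal 30 residues;
* else **rejected**.

The leader signature is `Phhx(1,2)h` with the hydrophobic set
{A, C, F, I, L, M, V, W, Y} (configurable — the class is stated in the
literature only as "hydrophobic"). The glycine requirement on doublets
is off by default since conserved doublets only *typically* include a
glycine; both modes are exposed. Bond-candidate mapping reports
conserved (unmasked, $H \ge 0.5$) S/T/D/E/K consensus positions in the
core region — defined as the columns after the last conserved doublet,
or the whole consensus when none exists — and conserved cysteines
separately as thioether (sulfur-donor) candidates. Connectivity between
bond candidates is deliberately not predicted.

The motif matcher supports residue classes (`[DE]`), wildcards (`x`) and
bounded variable gaps (`x(6-10)`), reports every alternative gap span,
and is validated against an independent regex-expansion oracle.

## Association statistics

Each locus is weighted by the reciprocal size of its anchor's tier-1
(90% identity) redundancy group, so a family's weighted frequency is the
fraction of *non-redundant* loci whose anchor directon contains it;
duplicating every locus changes no weighted frequency, which the suite
asserts to $10^{-12}$. Reported families must occur in more than 20 loci
and at least 1% of the weighted observations. Frequencies are kept as
fractions internally ("1%" = 0.01); the report renders both the fraction
and the percent form, since tabulated values of this kind are printed in
either convention.

"Closely spaced" genes are not quantified in the literature this
procedure derives from; the directon assembler defaults to a maximum
intergenic gap of 100 bp, a common operon-prediction heuristic, and the
knob is exposed in `pipeline_config()`.

## The synthetic locus generator

`generate_locus_set` emulates the study conditions end to end: three
divergent anchor branches (~300-residue enzymes), six precursor families
(two per branch; three instantiate cores from the bundled motif library
and classify as *known*, three carry novel cores and classify as *new*),
five ancillary families joining the anchor directon independently with
probabilities 0.6/0.4/0.3/0.15/0.05, decoy families at outer ranks, and
a configurable fraction of near-copy loci (every protein re-evolved at
1% per site) to exercise redundancy weighting. Families evolve along
random bifurcating trees with matrix-similarity-weighted substitutions;
rates are set so that within-family divergence stays at or below ~30%,
the regime the recovery claims are stated for. One locus anchors at a
contig edge, and one ancillary family is long *and* adjacent to the
anchor so the length rule is exercised.

What the generator does **not** emulate: insertions and deletions within
families (members are equal-length), compositional bias, gene calling
errors, fragmented contigs, and trans-encoded partners. Passing
recovery tests therefore demonstrates the pipeline's internal
consistency under controlled divergence, not performance on real
genomes, where alignment quality and annotation noise dominate.

## Numerical choices and problem sizes

* Score floor 1 before the log-ratio; distances clamped at 0; UPGMA and
  consensus ties broken lexicographically/alphabetically — every stage
  is deterministic, and two runs with one config produce byte-identical
  reports (the manifest records the config, input content hashes and
  per-stage counts, and deliberately no wall-clock timestamp).
* The recovery experiments run 20 replicates of 50 loci (~320
  neighborhood proteins each); oracle-equivalence checks use 500 random
  5–8-leaf matrices for UPGMA, 1000 random columns for the consensus,
  and 1000 random sequences per motif pattern. These sizes keep a full
  run of the suite in the minutes range on one core while leaving the
  statistical assertions well powered.
* Single-sequence clusters are legitimate degenerate alignments; empty
  filter results warn rather than error; a single-leaf tree serializes
  as a trivial newick.

## Known limitations

* Center-star alignment degrades for deeply diverged clusters; plug in
  an external aligner through `new_msa()` where that matters.
* The Karlin–Altschul gate uses fixed gapped-BLOSUM62 constants rather
  than per-profile estimates; profiles with strong composition bias
  would deserve recalibrated parameters.
* Greedy centroid clustering is order-dependent by construction; the
  deterministic processing order makes runs reproducible but is still a
  heuristic, as in the tools it emulates.
* The iterative profile-refinement loop of a full profile search is
  abstracted to a single pass; `scored_profile`/`profile_score` form the
  documented seam where iteration could be added.
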