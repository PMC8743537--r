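---
title: "Classifying bacteria-infecting ssRNA phages with levitax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bacteria-infecting ssRNA phages with levitax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The classification problem

Bacteria-infecting positive-sense single-stranded RNA viruses (class
*Leviviricetes*; MS2 and Qbeta are the classic isolates) share a compact
genome encoding three core proteins: a maturation protein (MP), a coat
protein (CP) and an RNA-directed RNA polymerase (RdRP). Metatranscriptomic
surveys produce thousands of contigs that may belong to this class, and
the 2021 ICTV reorganization established a quantitative ladder for placing
them:

1. **Class membership** — the genome encodes all three core proteins, and
   is *coding-complete* when the MP is at least 350 aa and the RdRP at
   least 500 aa (inclusive thresholds).
2. **Order** — membership of the RdRP in one of two profile-HMM clusters:
   RdRP_A implies *Norzivirales*, RdRP_B implies *Timlovirales*.
3. **Family** — membership of the CP in one of nine clusters, each mapped
   to one of six families (e.g. CP_A/CP_B/CP_H to *Fiersviridae*,
   AP205-like to *Duinviridae*). When the CP-implied family belongs to a
   different order than the RdRP-implied order, the genome is
   *incongruent* and both ranks are left `Unassigned`.
4. **Genus / species** — pairwise amino-acid identity (PAAI) of the RdRP:
   50 % demarcates genera and 80 % species.

`levitax` implements this ladder end to end: ORF calling, profile-HMM
construction and scanning, Markov clustering for building cluster
libraries from scratch, PAAI demarcation, neighbor-joining trees with
clade-concordance reports, and a synthetic-genome simulator used to
validate the whole chain against planted truth.

## Profile HMMs

Profiles follow the Plan7 state layout (match/insert/delete per node) and
are built from a multiple alignment:

* a column becomes a **match state** when at least `match_fraction`
  (default 0.5, the standard heuristic) of rows are non-gap;
* **match emissions** are observed residue frequencies blended with a
  background pseudocount: `(freq + w * bg) / (1 + w)` with
  `pseudocount_weight` `w = 1` by default. Pseudocounts act on the
  frequency scale, so duplicating alignment rows leaves the profile
  unchanged;
* **insert states** emit the background distribution, and transitions are
  estimated from the per-row gap pattern with Laplace (+1) smoothing per
  outgoing group. Sequence weights are uniform (tree weighting is an
  extension point). Gap patterns that would need the I→D or D→I moves —
  which the Plan7 topology lacks — carry no count.

The background is a fixed Robinson–Robinson-style amino-acid frequency
vector bundled with the package.

Scoring is **global in the model, local in the sequence**: a query aligns
to the full profile, while flanking residues are emitted at background
frequency by N/C flank states whose loop transitions are free. Flanks
therefore contribute exactly zero bits, and the score is the log2-odds
`log2 P(path, seq | hmm) / P(seq | background)`. This makes the model
slightly improper as a generative HMM (the flank length is not
penalised), but keeps scores self-contained, deterministic, and
independent of any E-value calibration; the test suite checks both
Viterbi and forward scores against exhaustive path enumeration under
exactly these semantics. Ambiguous residues (`X`) emit the background in
every state and so contribute zero bits. There is no bias (null2)
correction; acceptance is a per-profile bit-score threshold, default 25
bits, stored in the HMMER3 `GA` line. We do not attempt to reproduce
HMMER's own bit scores; the HMMER3 ASCII reader/writer exists for
interoperability with externally built libraries.

## Protein clustering

Cluster libraries are rebuilt from any protein set with plain Markov
clustering (MCL) on an all-vs-all Smith–Waterman similarity graph
(BLOSUM62, gap open 11 / extend 1, a gap of length L costing
`open + L * extend`; edges below score 30 are dropped as noise). We use
plain MCL rather than the full orthoMCL pipeline because the inputs are
one pooled sequence set — the species-aware reciprocal-best-hit
normalisations of orthoMCL have nothing to act on. Defaults: inflation
2.0, pruning threshold 1e-5, at most 100 iterations, convergence
tolerance 1e-6; self-loops are weighted with each node's maximum incident
weight. Anchor sequences can transfer the established cluster labels
(CP_A…CP_H, AP205-like, RdRP_A/RdRP_B, MP_1–MP_3 — the MP clusters were
counted but never named in the original description, so we number them);
unanchored clusters get `novel_<role>_<k>` labels.

## PAAI and demarcation

PAAI is computed from a global Needleman–Wunsch alignment with affine
gaps (BLOSUM62, 11/1) as `100 * identical / aligned` columns, where
**aligned columns exclude terminal-gap overhangs** but include internal
gap columns. The denominator choice is deliberate and is the one place
where reasonable definitions disagree: excluding overhangs avoids
penalising contigs whose ends are truncated, while internal gaps still
count against identity. Borderline cluster memberships can move under a
different denominator, so the rule is stated prominently here and in
`?paai`. Traceback ties are broken deterministically (substitution, then
gap in the first sequence, then gap in the second).

Demarcation is **single-linkage**: genera are connected components of the
"PAAI ≥ 50" graph, species of the "PAAI ≥ 80" graph computed within each
genus. Single linkage is the unique rule that makes "PAAI above the
cut-off" itself the demarcation criterion, and computing species within
genera guarantees by construction that every species nests inside exactly
one genus. Thresholds are inclusive (the criteria are stated as minima,
not strict bounds). Exemplars are selected per cluster by decreasing
priority — ICTV-archived, then GenBank-deposited, then longest contig —
with ties broken by contig length then id.

When a new genome is classified against a demarcated reference set, the
query adopts the genus of its best reference match at ≥ 50 % PAAI, then
the species of its best match within that genus at ≥ 80 %; otherwise it
founds a deterministic `novel_genus_<k>` / `novel_species_<k>`.

## Phylogeny

Trees are built by Saitou–Nei neighbor joining over `1 - PAAI/100`
distances. Neighbor joining over the already-computed PAAI distances is a
deliberate methodological substitution: it keeps the pipeline
self-contained and deterministic, and it is exact on additive matrices
(property-tested). Negative branch estimates are clamped to zero with the
deficit moved to the adjacent branch. Clade concordance between the tree
and a labelling (e.g. HMM-predicted orders) is assessed per label as an
unrooted bipartition test; for non-monophyletic labels the minimal leaf
set whose removal restores monophyly is found exactly by scanning all
bipartitions — every repair corresponds to the symmetric difference
between the label set and some bipartition side, so the scan is exact at
any size (no heuristic fallback is needed). The disagreement count is the
number of distinct outlier leaves across labels.

## The synthetic-data generator

`simulate_reference_set()` emulates the structure the classifier is built
for: per order one RdRP cluster and one MP cluster, per family one CP
cluster; cluster ancestors are drawn at background composition (MP 400
aa, CP 130 aa, RdRP 540 aa — typical leviviricete lengths, and safely
above the 350/500 completeness floors). The identity ladder plants genus
ancestors at ~40 % pairwise identity within their cluster, species
ancestors at ~70 % within genus, and members at ~90 % within species, so
both demarcation thresholds are bracketed with ~10-point margins
(per-branch identities are the square roots of the pairwise targets).
Mutations are BLOSUM62-weighted substitutions; the generator runs
indel-free by default so that planted margins can be asserted from direct
positional identity, which then coincides with aligned PAAI. Proteins are
back-translated with uniform synonymous codons under the bacterial code
(11) — no codon-usage model, since every downstream stage is
protein-level — and concatenated MP–CP–RdRP with stop codons and short
spacers that place an in-frame stop immediately upstream of each gene, so
the planted ORFs are exactly recoverable. Generation asserts the planted
margins on the RdRP (inter-genus < 50, within-genus cross-species strictly
between 50 and 80, within-species > 80) and regenerates, up to five
attempts, if a random draw violates them.

What the simulation does **not** emulate: indel-rich divergence,
compositional bias, codon usage, RNA secondary structure, fragmented or
chimeric assemblies, and sequencing error. Passing the recovery tests
therefore demonstrates the internal consistency of the decision ladder at
realistic divergence levels, not robustness to every artefact of real
metatranscriptomic data.

## Validation scale and numerical choices

The test suite validates, among others: Viterbi/forward equality with
exhaustive path enumeration on all profiles with up to 3 match states and
queries up to 3 residues (tolerance 1e-9 log2 units); full-chain recovery
of every planted rank on the 2 orders × 3 families × 4 genera × 3
species × 2 members condition (144 genomes) across five seeds; threshold
nesting on 100 random PAAI matrices; neighbor-joining exactness on 50
random additive matrices of 4–12 taxa; Markov-cluster recovery of planted
families; a 1000-pair fuzz of the incongruence rule; and HMMER3
round-trip stability to 1e-5. These sizes keep the default run
desk-scale while exercising every decision path; `scripts/acceptance.R`
re-runs the main chain at the same 144-genome condition.

Degenerate inputs are handled explicitly: empty FASTA files, duplicate
ids and illegal characters are errors with positions; genomes with no
ORFs or no passing HMM hits produce `Unassigned` calls rather than
failures; alignments in which no column reaches the match fraction are
rejected at profile-build time; `X` residues are neutral everywhere.

## Known limitations

* Bit-score thresholds (default 25) substitute for E-values; profiles
  built from very small or very diverse clusters may need per-profile
  tuning via the `GA` field.
* PAAI depends on the stated alignment parameters and denominator;
  sequences near a threshold can change sides under different choices.
* The `build-hmms` subcommand aligns cluster members to the longest
  member as an anchor (inserts relative to the anchor are dropped) — a
  documented simplification adequate for profile training, not a general
  multiple aligner.
* Order and family are reported (flagged incomplete) even for genomes
  failing the completeness filter, but such genomes are excluded from
  genus/species demarcation.
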