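---
title: "Methods and design of the clockcost pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the clockcost pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clockcost` quantifies the molecular correlates of the bacterial protein
molecular clock — how structure, solubility proxies, and evolutionary
rates relate to gene expression — and the fitness cost of gratuitous
protein synthesis. This vignette documents the models and procedures,
the parameters that matter, the synthetic-data generators that stand in
for external datasets, and the numerical and design choices made where
alternatives existed.

## Structural descriptors

**Contact definition.** Two residues are in contact when any pair of
their non-hydrogen atoms is strictly closer than 4.5 Å and their
sequence separation is at least `min_separation = 2`, the minimal
reading of "non-adjacent" (self and immediate neighbours excluded). Each
residue pair counts once, however many atom pairs qualify.

**Contact density and contact order.** Contact density is `N / L`,
with each contact counted once; some authors count both directions
(`2N / L`), which only rescales the descriptor and leaves rank
correlations unchanged. Contact order is `(L·N)⁻¹ Σ (j − i)`. The
separation convention `ΔS = j − i` matches standard relative
contact-order usage; an alternative reading ("residues separating the
pair", `j − i − 1`) is exposed as `separation_offset = 1`. Contact
order lies in (0, 1] whenever at least one contact exists; structures
with no contacts raise an error and are excluded from contact-order
statistics rather than silently contributing zeros.

**Solvent accessibility.** Absolute per-atom SASA uses the
Shrake–Rupley test-point construction: points spread quasi-uniformly
(a deterministic golden-spiral lattice) on the probe-expanded sphere
(van der Waals radius + 1.4 Å probe), a point being accessible unless
it falls inside a neighbour's expanded sphere. Boundary points count as
occluded, so exactly coincident atoms bury each other instead of
raising an error. Van der Waals radii are a fixed element table
(C 1.70, N 1.55, O 1.52, S/P 1.80 Å; unknown elements fall back to
carbon). The default 960 points per atom gives isolated-sphere areas
exact to numerical precision and, on the package's fixtures, an
accessible-fraction change below 0.5% when the point count is doubled.
Because the point lattice is fixed in the laboratory frame, SASA is
rotation invariant only up to discretization (about 1–2% at 960
points); contact-based descriptors are rotation invariant to 1e-9.

**Relative accessibility and burial.** Residue SASA is divided by a
residue-type maximum from the Tien et al. (2013) theoretical table,
embedded in the package; the burial threshold is relative accessibility
strictly below 0.16. Both the table and the threshold are arguments,
since burial conventions differ across programs. Residue types without
a reference (X) get `NA` and are excluded from burial statistics.

**Residue classes.** Charged = {D, E, K, R} — histidine is excluded as
pH-ambiguous — and hydrophobic = {A, V, L, I, M, F, W, C}. Both sets are
arguments; analyses that want H charged can pass it in.

**Secondary structure.** When no DSSP-format file is supplied, a
simplified three-state assignment from backbone dihedrals is used:
helix for φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°] in runs of ≥ 4; strand for
φ ∈ [−180°, −80°] with ψ ∈ [80°, 180°] or ψ ∈ [−180°, −170°] in runs of
≥ 3; otherwise coil. Dihedrals are wrapped to [−180°, 180°) so a fully
extended chain (φ = ψ = 180°) reads as strand. This assignment is
approximate — it has no hydrogen-bond term — and is intended for the
package's idealized fixtures and as a fallback; the loop fraction is
the share of residues outside {H, G, I, E, B}.

**Redundancy filter.** The 90%-identity filter is a greedy scan in
input order: a sequence is dropped if its global-alignment identity to
any already-retained sequence exceeds the cap, guaranteeing all
retained pairwise identities ≤ 0.90. Greedy order-dependence is
accepted for determinism.

**PDB parsing.** The parser keeps the first model only, skips HETATM
and waters, drops hydrogens/deuteriums, resolves alternate locations by
highest occupancy (ties by altloc identifier), renumbers residues
1..L in order of appearance with insertion codes collapsed, and retains
residues lacking CA while flagging them. Malformed coordinate fields
fail with the offending line number.

## Sequence evolution

**Alignment.** Global Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment`, scored BLOSUM62 / gap open 11 /
extend 1 (protein-BLAST-like defaults). Identity is identical columns
over columns where neither sequence is gapped (BLAST "identities"
semantics); coverage is each sequence's aligned non-gap length over its
own length — requiring both coverages ≥ 0.80 is the symmetric, stricter
reading of "alignable over at least 80% of their total length".

**Ortholog pairing.** Reciprocal best hits on alignment score; a gene
whose best score is tied between candidates is dropped rather than
paired (conservative orthology). The output is symmetric in the order
of the two proteomes.

**Ka/Ks.** The Nei–Gojobori (1986) counting estimator with Jukes–Cantor
correction. Per-codon synonymous site fractions come from the universal
code; single-nucleotide changes that would create a stop codon count as
nonsynonymous in the site tally, which keeps the invariant
`S + N = 3 × codons` exact. Site counts of a codon pair are averaged
over the two sequences. Codon pairs differing at 2–3 positions are
resolved by averaging the synonymous/nonsynonymous split over all
minimal mutational pathways whose intermediates are sense codons; if
every pathway passes through a stop, the pair is skipped and counted in
a `skipped_codons` diagnostic. Proportions `ps`, `pn` at or above 3/4
raise a saturation error instead of returning a complex rate. The
estimator tag (`NG86+JC`) is stamped into results and pipeline output
metadata because maximum-likelihood codon models (e.g. PAML) are the
common alternative and give systematically different absolute rates;
counting methods are self-contained and desk-verifiable, which is what
this package optimizes for.

**Paralogs.** Candidate duplicates are unordered pairs with identity
strictly above 0.40 and both coverages at least 0.80. The
expression-consistency filter computes, per pair, the larger fraction
of experiments in which one member is strictly higher (ties count for
neither) and retains the pair only when that fraction strictly exceeds
0.80 — "more than 80% of experiments".

**Codon preference.** Percent usage of each sense codon within its
synonymous family over a user-supplied reference CDS set; families
whose amino acid never occurs are reported missing rather than zero.

## Association statistics

Spearman correlations use midranks throughout. P-values: for n ≥ 20 the
t approximation on n − 2 df; for n ≤ 7 exact enumeration over all
permutations; between, a seeded Monte-Carlo permutation test with 10⁴
draws (the +1 correction makes its p-values strictly positive). The
first-order partial correlation uses the pairwise-r formula (not
rank-residual regression) with a t test on n − 3 df; a control variable
rank-identical to x or y raises a degenerate-control error.

The paired signed-rank test enumerates the exact sign-flip null by
convolution for up to 25 nonzero differences — doubling midranks to
integers, so tied magnitudes stay exact — and otherwise uses the normal
approximation with tie and continuity corrections. The Mann–Whitney
test is exact (via the U null distribution) when the smaller group has
≤ 8 observations and no ties. Two-sided p-values are twice the smaller
tail, capped at 1. Reported p-values are floored at 1e-15; a printed
"< 1e-15" replaces zero.

Missing data are removed pairwise (or triple-wise for partials), and
every result carries the n actually used. No multiple-testing
correction is applied; the suite reports the number of tests so the
reader can apply one.

Regression slopes come from `stats::lm` with a two-sided t test; a
constant response returns slope 0 with p = 1, and a perfect fit reports
the p floor. Slope differences use a Welch t with Satterthwaite df.
The moving-average trend sorts by x and emits each consecutive
window's mean (window 200 by default, matching the smoother drawn
through expression scatter plots at genome scale).

## Growth and synthesis rates

Growth rate is the OLS slope of the natural log of OD600 on time;
"logarithm" without a base only rescales the rate, and natural log
makes the rate the continuous-time exponential coefficient. Any
pre-growth lag is the data producer's concern; an optional `t_min`
argument drops early samples. Relative cost is
`100 (rate_ref − rate)/rate_ref`, negative when a strain grows faster
than the reference. Replicate comparisons report per-strain mean and
SEM (`sd/√n`, undefined and flagged for single replicates) and pairwise
Mann–Whitney tests. Synthesis rates are per-strain OLS slopes of band
intensity on time (linear scale — intensities are already relative
measures), compared by the Welch slope test.

## Synthetic-data generators

All generators draw from a private seeded stream and never touch the
caller's RNG; the same seed gives bit-identical output.

**Structures** are idealized poly-alanine (backbone N, CA, C, O plus
CB) built from ideal bond geometry and prescribed dihedrals: fully
extended chains (no non-adjacent contacts, consecutive CA 3.80 Å),
ideal α-helices, two-strand antiparallel hairpins registered so residue
i faces residue L+1−i across a 4.6 Å gap, and CA-only random packed
clusters (minimum spacing 3.8 Å, user-specifiable positions). The
generator's ground-truth contact set is enumerated directly from the
emitted coordinates. These fixtures make geometry auditable; they do
not emulate real folds, side chains, or crystallographic artefacts, so
passing tests validate the descriptor computations, not biological
realism.

**Coding pairs** evolve a random sense-codon ancestor by uniform
single-nucleotide proposals: synonymous changes always accepted,
nonsynonymous accepted with probability ω, stop-creating proposals
rejected, until the accepted synonymous count reaches
`round(target × S_sites)`. The realized accepted counts are returned,
giving an internal oracle for Ka/Ks recovery (`Nd/Sd ≈ ω · N/S`). The
generator has no codon-usage bias or rate heterogeneity.

**Gene tables** come from a Gaussian copula with the exact
Spearman-to-Pearson conversion `ρ = 2 sin(π r_s / 6)`, so planted rank
correlations survive the monotone marginal transforms (log-normal
meanlog 2 / sdlog 1 for expression; uniform for solubility fractions;
Beta(2, 5) for composition fractions). The matrix square root uses the
eigendecomposition so positive-semidefinite (not just definite)
targets work. The default target structure mirrors the expression
associations the pipeline is designed to measure (expression–Ka −0.45,
Ka–Ks +0.66, expression–solubility +0.27, expression–charged +0.28,
expression–Ks −0.50). Real transcriptome covariance beyond these
pairwise targets is not emulated.

**Paralog families** derive a second gene by random codon
substitutions until pairwise identity lands within ±2 percentage
points of the target (identity only decreases, so with proteins of
≥ 100 residues the landing window is always reachable; short proteins
can overshoot and raise a generation error). Expression matrices make
one member strictly higher in exactly `round(consistency × n)`
experiments, with a ±1.5-fold ratio so no ties occur. The default 466
pseudo-experiments match the multi-condition compendium scale the
consistency filter is meant for.

**Growth curves** are `od0 · exp(rate·t) · exp(ε)`, ε ~ N(0, sd²)
i.i.d. per time point — multiplicative noise on an exponential, with
default sampling every 45 minutes over ~5 h and `noise_sd = 0.01`
(about 1% OD error). No lag or stationary phase is simulated, matching
the estimator's pure-exponential window.

## Problem sizes and defaults

The shipped configuration uses 2000-gene tables (4000 in the
recovery checks), 300–500-codon coding pairs, 30-residue structures at
960 sphere points, triplicate growth curves, and tens of seeds per
Monte-Carlo recovery check. These sizes put empirical rank correlations
within ±0.05 of their targets and mean growth-rate errors under 2%,
while a full end-to-end run completes in seconds on one core.

## Known limitations

- The dihedral secondary-structure assignment is a fallback, not a
  DSSP replacement; with real structures, supply DSSP output.
- NG86 counting underestimates rates at high divergence relative to ML
  codon models; comparisons across methods should use one estimator
  throughout.
- The all-vs-all alignment steps (reciprocal best hits, redundancy
  filter, paralog search) are quadratic and meant for desk-scale sets,
  not whole proteomes.
- Absolute correlation values from real expression/solubility datasets
  depend on dataset and preprocessing choices; this package's recovery
  guarantees are for its own generators, where ground truth is known.
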