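---
title: "Methods: detecting co-transcriptional mRNA imprinting and its kinetic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting co-transcriptional mRNA imprinting and its kinetic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
```

This vignette is the package's account of its models, conventions and
design choices: what each statistic assumes, which parameters matter
and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and where the methods are known to
break down.

## Coordinates and containers

All internal coordinates are 0-based and half-open. The polyadenylation
site (pA) is the *exclusive* transcript end: the first base not in the
transcript, in transcript sense. On the minus strand the TSS coordinate
is therefore numerically larger than the pA and the transcript occupies
the genomic interval `[pa, tss)`. This convention is BED-native and
eliminates off-by-one ambiguity when windows are anchored at gene ends:
the window offset 0 at the pA anchor is the first base past the
transcript, offset −1 the last transcribed base.

Signal lives in a `signal_track` (one non-negative value per base and
strand; unstranded assays are mirrored onto both strands), and anchored
analyses go through `signal_matrix` objects: genes × offsets, always
oriented 5'→3' in transcript sense. Cells that fall outside a
chromosome are *masked*, not zero-filled, and every averaging operation
divides by the per-column count of valid cells — zero-filling would
bias edge columns downward, which matters for short transcripts in
pA-anchored windows. bedGraph is the canonical track format (text,
diff-able); BED and GFF3 annotations of the same locus parse to
identical objects.

## The hybrid-scale metagene

`scaled_metagene()` averages signal on a hybrid axis: flanks at real
scale (bp), the transcript body resampled to a fixed number of bins
(default 100, i.e. percent of gene length). Body resampling uses
mean-within-bin rather than interpolation so that the binned profile
preserves read-density semantics — the profile of a constant track is
exactly constant regardless of the gene-length mix, and a peak at a
fixed *fractional* position contributes to the same bin for a 400 bp
and a 4000 bp gene. Genes shorter than the bin count are skipped and
reported. The robust filter (`robust_filter()`, default 5%) removes the
most extreme genes by mean coverage before averaging; the 5% is split
evenly between the high and low tails — the even split is this
package's convention and is recorded in the result's attributes.

## CRAC+ classification

The classification pipeline is: per-gene counts → top-N selection
(default 600, ties broken lexicographically) → pA-anchored matrix
(default −500..+100, the window and its 10 bp bin width are
config-exposed choices) → shape normalization → k-means (default k = 4,
`stats::kmeans` with a fixed seed and 10 restarts) → cluster-level
call.

**Shape normalization.** Each row is divided by its in-window mass so
that clustering sees binding *shape*, not expression level. Plain
unit-mass scaling, however, inflates near-empty rows into spurious
spikes: a gene with two stray background reads upstream of the pA then
looks like a strongly pA-proximal profile, and k-means will happily
collect such rows into a false "bound" cluster. The package therefore
smooths each row toward the *uniform* profile before scaling — a
symmetric Dirichlet prior with total pseudocount
`max(0.1 × Q3 of row masses, 5)`, where Q3 makes the amount of
smoothing scale-free (multiplying the track by a constant does not
change labels) and the floor of ~5 reads encodes that below roughly
five reads a profile carries no usable shape information. Low-evidence
rows are thus pulled to the null (flat) shape, whose upstream mass
fraction (250/600 ≈ 0.42 for the default window) sits safely below the
call threshold; a background-only cohort yields an empty call rather
than noise-driven positives. The uniform profile is a fixed point of
the smoothing, so mass-fraction arithmetic on flat clusters is exact.

**The call.** Clusters are relabeled by decreasing mass fraction of
their mean profile in the 250 bp upstream of the pA, and every cluster
above the threshold (default 0.6) is CRAC+; the call is the union of
their genes. The threshold is deliberately a first-class parameter with
a sensitivity sweep (`threshold_sweep()`) because any single cut-off on
a continuous mass fraction is somewhat arbitrary; the cluster report
carries the fraction of all reads falling in CRAC+ clusters as a
global sanity statistic. The `crac_index()` (CRAC RPKM / mRNA level,
optionally / ChIP signal) flags zero denominators instead of dropping
genes.

Known limitation: the cluster-level call inherits k-means' tendency to
find structure in sparse noise. The Dirichlet smoothing suppresses this
for rows far below the cohort's typical signal, but in a cohort where
*every* row has only a handful of reads (no top-N enrichment at all),
mass-fraction calls on clusters should not be trusted.

## Motif scanning

`scan_gct_repeats()` reports maximal non-overlapping runs of ≥ 2
contiguous `GCT` units (unit and minimum both parameters), scanning
greedily left to right exactly like the regular expression
`(GCT){2,}`; the test suite holds the scanner byte-identical to that
oracle exhaustively over all short strings. Runs containing `N` break
at the `N`. Distances upstream of the pA are measured to the run
*midpoint* — start-vs-centre is genuinely ambiguous for this kind of
summary statistic, and the midpoint is invariant to extending a run
symmetrically; the choice is recorded here and in the output. The
default scan window (160 bp upstream of the pA, clipped at the TSS)
matches the scale at which such motifs concentrate; positional
recovery tests use a wider 250 bp window so that the planted distance
distribution (mean 150, sd 25) is not truncated. Motif presence is
compared between gene sets with the exact hypergeometric machinery
below. De novo motif discovery is out of scope — the scanner is
parameterized, not learned.

## Steady-state and time-course kinetics

Under steady state, abundance = synthesis rate × half-life, so
`half_life_steady_state()` computes HL = RA / SR in arbitrary units and
flags SR = 0 genes rather than erroring. HL is exactly invariant to
rescaling SR and RA by a common factor, which is why arbitrary units
suffice for all ratio- and rank-based downstream analyses.
`condition_ratio()` forms per-gene B/A (or log2) ratios of SR, RA or HL
over the shared gene universe; degron-style analyses are summarized as
distribution shifts (median ratios per gene set) rather than per-gene
significance calls, matching the scatter/density style of presentation
this mirrors.

Explicit decay courses are normalized to a reference transcript
(a Pol III product untouched by Pol II transcription arrest) and scaled
to 100% at t = 0. `fit_decay_halflife()` fits ln(percent) against time
by ordinary least squares and returns ln 2 / |slope|. Log-linear least
squares was chosen over a nonlinear exponential fit because 3–5 point
courses do not constrain a nonlinear fit well; slopes at or above
numerical zero (≥ −1e−12) are flagged "no decay" rather than converted
into absurd half-lives, and non-positive points are excluded with a
warning before taking logs.

## Backtracking index

Backtracked Pol II is crosslinkable (ChIP sees it) but cannot elongate
(run-on does not), so the ratio BI = ChIP / GRO rises with the
backtracked fraction: in the generator's terms BI ∝ 1/(1 − b). Per-gene
signals are the mean of 5' and 3' 250 bp tile means — the tiles are the
assay's native resolution, and how they combine into one BI is not
canonical, so both tile means are also returned. Genes shorter than a
tile fall back to the whole-gene mean and are flagged. The pseudocount
defaults to 0 with zero-GRO genes flagged as undefined; analyses of
noisy array data can set it explicitly. `zscore_median()` — centre on
the median, scale by the sample SD about the mean — makes BI comparable
across assay types; median-centring with mean-based SD is the
documented reading of "median and standard deviation" normalization,
and a MAD-based variant would change only the scale, not the ranking.

## Rpb4/Rpb3 stoichiometry

Two deliberately different ratio conventions coexist and are kept
separate:

- `ratio_profile()` (per-position, across a gene set) uses the **ratio
  of means**: average Rpb4 signal across genes divided by average Rpb3
  signal, per position. This is robust to per-gene zeros and matches
  how set-level profiles are usually drawn. The two segments (−100..+250
  of the TSS, −250..+100 of the pA) are normalized to the TSS −100
  position, so the profile reads as "change after Pol II recruitment"
  and its anchor value is exactly 1 by construction.
- `body_ratio()` (per-gene scalar) uses the **mean of per-position
  ratios** over the TSS..+250 and −250..pA windows, the per-gene
  averaging convention.

Both accept a pseudocount; the default is 0, with undefined positions
(zero denominator) excluded as NA, so that noiseless closed-form checks
hold to 1e−9 — a data-driven pseudocount (e.g. a percentage of the
positive median) is available to callers working with noisy tracks but
would bias exact recovery and is therefore not the default.

`correlation_ledger()` computes Pearson and Spearman coefficients with
two-sided `cor.test` p-values for requested quantity pairs, stratified
by gene set, over pairwise-complete observations with n reported. No
multiple-testing correction is applied within the ledger — it mirrors
per-panel reporting — and that fact is part of the output contract.

## Gene-set statistics

`hypergeom_overlap()` returns both tails: inclusion P(X ≥ k) (the upper
tail *includes* the observed k — tail conventions differ between tools,
so this is stated) and exclusion P(X ≤ k), with fold = k / E[X]. The
universe is always explicit; defaulting silently to the union of the
sets changes p-values drastically and is refused. `venn_counts()`
covers 2–3 sets with an outside-universe check, and
`annotation_enrichment()` applies Holm–Bonferroni step-down adjustment
per term via `p.adjust`.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is validated against:

- 600 genes (the size of a top-600 analysis universe), 262 of them
  CRAC+ (~44%), on 2 chromosomes, transcript lengths 600–2500 bp,
  intergenic gaps ≥ 400 bp so that flanking windows of neighbours never
  overlap.
- CRAC+ genes receive a Gaussian pile of Poisson reads centred
  150 ± 20 bp upstream of the pA (within-gene spread 30 bp), ~50 peak
  reads per gene, over a uniform background of 0.0015 reads per
  transcribed base. The background rate is calibrated so that the peak
  clusters hold ~98% of window reads, the split reported for the real
  classification this emulates; genes whose sampled offset does not fit
  are resampled.
- `(GCT)n` motifs are planted in 65% of CRAC+ genes at a centre
  distance of 150 ± 25 bp upstream of the pA; chance runs in every
  gene's scan window are first purged (one base of every second unit is
  rewritten) and units flanking a planted motif are broken, so scanner
  hits equal planted truth exactly.
- Expression tables satisfy RA = SR × HL × lognormal(mean 1, CV
  `noise_cv`); the mutant-like condition multiplies the HL of CRAC+
  genes by 0.5 (or a per-gene vector, used for coupled designs).
- ChIP/GRO tracks encode a per-gene backtracked fraction b ~ U(0.1,
  0.7): ChIP ∝ load, GRO ∝ load × (1 − b); the mutant-like condition
  halves b in CRAC+ genes. In the coupled study wrapper the mutant HL
  multiplier is (1 − b_wt)/(1 − b_mut), so factor-dependence of BI and
  of HL correlate in CRAC+ genes only — the qualitative structure the
  correlation ledger is designed to detect.
- Rpb4/Rpb3 tracks: Rpb3 flat per gene, Rpb4 declining linearly with
  distance from the TSS (per-kb slopes per condition and gene class, or
  an exact end-ratio for closed-form checks), ratio 1 upstream of the
  TSS and frozen at its end value past the pA.

Poisson counts and multiplicative lognormal noise are the simplest
generative models consistent with count tracks and array-style ratios;
the default assay noise is CV = 0.1. Every generator takes a seed and
restores the caller's RNG state; identical seeds give byte-identical
output.

What the generator does **not** emulate — and hence what green tests do
*not* establish about real data: mappability and GC artefacts,
UTR/isoform structure and alternative pA sites, splicing, crosslinking
sequence bias, probe effects in array ratios, correlated noise between
conditions, and any coupling between expression level and binding other
than the planted ones. Results on real data additionally depend on the
annotation's pA quality, which the package treats as given.

## Problem sizes and numerical choices

The shipped test-suite and acceptance runs use the defaults above
(600-gene simulations; 100-replicate loops at 150 genes for the
repeated backtracking comparison and 100 replicates for decay fitting),
sizes chosen so the full validation completes in a few minutes on one
CPU while keeping every planted effect comfortably resolvable.
Noiseless closed-form checks are asserted to 1e−9 (profile endpoints,
body ratios) or 1e−12 (half-life identities, hypergeometric closed
forms); seeded stochastic checks use the thresholds stated with each
test. Ties in top-N selection and in the robust filter are broken
lexicographically by gene id so that every pipeline stage is
deterministic under a fixed seed.
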