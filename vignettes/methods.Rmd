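---
title: "Models and methods behind chaoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chaoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chaoscope` analyses peripheral-blood CD8⁺ T cells along five axes — subset
composition, TCR repertoire, transcriptional modules, protein-level
pseudotime, and a clinical quadrant biomarker — and ships a synthetic-cohort
generator so each stage can be validated end to end. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not demonstrate about real data.

## Subset gating

Cells are partitioned on CCR7 × CD45RA into naive (Tn, CCR7⁺CD45RA⁺),
central memory (Tcm, CCR7⁺CD45RA⁻), effector memory (Tem, CCR7⁻CD45RA⁻) and
CD45RA-re-expressing effector memory (Temra, CCR7⁻CD45RA⁺); Tem and Temra
are subdivided on CD27 × CD28 into DP, SP27, SP28 and DN. Manual gates are
replaced by automatic positivity thresholds: per marker and batch, a
two-component Gaussian mixture is fitted on `asinh(x / cofactor)` intensity
(cofactor 150, the conventional fluorescence-scale choice) and the cutoff is
placed where the posterior probability of the upper component crosses 0.5,
mapped back to the raw scale. Degenerate fits — components separated by less
than one pooled standard deviation, or near-constant data — fall back to a
quantile cutoff with a warning. Mixture fitting runs on a seeded subsample
(default cap 20,000 cells per marker-batch) for speed; the cutoff is
insensitive to the subsample at that size. The tie rule is `intensity ≥
threshold ⇒ positive`, so the partition is exhaustive and deterministic.

Relative MFI divides each (donor, subset, marker) mean raw intensity by the
reference healthy donor's Tn mean for the same marker and batch. This
cancels any per-batch multiplicative distortion exactly (a property the
tests assert), which is the reason the assay design keeps one healthy
reference in every experiment; a reference missing from a batch is an error,
not a silent gap. MFI uses the arithmetic mean by default (geometric
available).

## TCR repertoire

A clonotype is the concatenation of the CDR3α and CDR3β amino-acid
sequences; cells missing either chain are excluded from clone statistics and
counted in a QC report, and multi-contig cells keep the highest-abundance
productive contig per locus (the common droplet-data convention). Shannon
diversity uses natural logs; Pielou evenness is `J = H / ln S` for `S ≥ 2`,
and clonality is defined as `1 − J` (the standard reading; a
single-clonotype repertoire is maximally clonal by convention, `J = 0`).
Expansion classes are barely (size 1), intermediate (2–10) and heavily
(> 10) expanded; the "more than ten" boundary is configurable. VDJdb
matching is exact string equality after uppercasing, requiring both chains
of a clone to match database entries that share the same epitope — no
Hamming tolerance, because near-matching is a different (prediction)
problem.

One caution surfaced by exhaustive small-case enumeration: transferring a
cell from a small clone to the largest clone always raises clonality *only
while the source clone survives* (Schur-concavity of entropy at fixed `S`).
If the transfer empties a singleton, `S` itself drops and clonality can
fall — `[1, 5, 5] → [6, 5]` moves clonality from 0.149 to 0.006. The test
suite asserts the well-posed form.

## Module scoring

Per-cell gene-set scores follow the binned-control scheme: all genes are
ranked by pooled mean expression into `n_bins = 24` equal-size bins; each
target gene draws up to `n_ctrl = 100` control genes from its own bin
(excluding the target set itself, so a one-gene set against a two-gene bin
reduces to the pair difference); the score is the per-cell mean of targets
minus the mean of controls. Control draws are seeded. Scores are invariant
to adding a per-cell constant, and random gene sets score zero in
expectation — both asserted as properties. Donor-level analysis averages
scores over a chosen cluster's cells per donor, and relative scores subtract
the healthy-donor mean per set and dataset, making the healthy mean exactly
zero by construction.

Gene-set cluster (GSC) assignment is hierarchical clustering of the sets ×
donors average-score matrix under correlation distance with average linkage,
cut at `k = 4`; cluster labels are ordered by decreasing mean
patient-minus-healthy score so GSC1 is the most patient-elevated group. The
published categorisation procedure is unstated, so this clustering is a
documented substitute, and `k` is a parameter rather than a constant. The
built-in gene sets (`builtin_gene_sets()`) are synthetic placeholders
matching the generator's programs, not a curated signature collection.

## Protein pseudotime

The trajectory is deliberately deterministic: markers are transformed to
`asinh(x / 150)`, z-scored (scaled, not normalised), projected onto `d = 5`
principal components; cells are joined in a symmetric `k = 15`
nearest-neighbour graph with Euclidean edge weights (neighbour ties broken
by cell index); pseudotime is the single-source shortest-path distance from
the root, min–max scaled to [0, 1]. The asinh transform matters: z-scores of
raw log-normal intensities are dominated by the bright right tails, which
hides drift among dim cells. Well-separated subset clusters can disconnect a
kNN graph, so components are joined by their shortest bridging edge
(deterministically) before distances are computed.

The root is the medoid of the naive cells. When donor groups are known, the
medoid is taken over *healthy* naive cells (`root_mask`): the healthy naive
state is the biological origin of the differentiation axis, and a
mixed-cohort medoid sits between the healthy and drifted patient naive
clouds, producing a V-shaped distance profile inside the root subset that
cancels the very shift being measured. Distributions are histograms over
`B = 50` equal-width bins of [0, 1], normalised per (group, subset);
patient-minus-healthy differences therefore always sum to zero. Per-subset
single-interval summaries are available through the per-donor averages; the
binned distribution is the primary representation.

## Quadrant biomarker

Thresholds are either fixed (NSCLC 36 / 17.2, SCLC 42 / 11, the published
healthy-quantile values) or re-derived as the empirical 0.8-quantile of a
healthy reference (type-7 linear interpolation; `≥ threshold ⇒ hi`, matching
the "higher than most healthy individuals" construction). Quadrants: Q4 =
DN-Tem lo / DP-Temra lo, Q1 = DN-Tem hi / DP-Temra lo, Q2 = hi/hi, Q3 =
DP-Temra hi / DN-Tem lo (the hi/hi orientation follows the published
quadrant sketch and is configurable).

Proportion CIs come in two flavours because the published intervals
demonstrably mix them: Wald (`p̂ ± 1.96·√(p̂(1−p̂)/n)`, intentionally
unclipped — an 11/12 rate legitimately prints an upper bound above 100%) and
Wilson. Every report carries both. Fisher's exact test uses the standard
probability-mass two-sided ordering; the suite verifies it against
exhaustive enumeration for every 2×2 table with `N ≤ 30`. ROC AUC uses the
midrank formula (equal to Mann–Whitney `U/(n₁n₀)`, ties counting ½), with
the predictor negated so that AUC > 0.5 means lower DN-Tem predicts
response; a Hanley–McNeil CI is optional. The Gehan–Breslow–Wilcoxon test is
implemented as the weighted log-rank statistic with weight equal to the
total number at risk (the `survdiff` rho-family weights by the survival
estimate instead, which is Peto–Peto, so the statistic is computed
in-package); Kaplan–Meier curves come from `survival::survfit`, and a
seeded permutation p-value is available for small samples.

## The synthetic generator

The generator defines the study conditions under which the package validates
itself. Defaults: 50 healthy donors and 50 patients, 5,000 cells per donor.
Per-donor subset composition is Dirichlet around the group mean
(concentration 100, giving realistic donor-to-donor spread); within-Tem
composition means are DP/SP27/SP28/DN = 0.40/0.15/0.15/0.30 for healthy and
0.25/0.125/0.125/0.50 for patients, so the configured DN-Tem group gap is
0.20. Stage-specific additive logit shifts on the DN fraction are available
(zero by default). Counts are apportioned by largest remainder so per-donor
subset counts match the sampled composition exactly.

Marker intensities are log-normal per (subset, marker), with positive modes
near `log 5000` and negative modes near `log 100` (sdlog 0.35) and graded
non-gating markers (CD95 rising, CD73/CXCR4/CXCR3 falling along
differentiation) so a monotone protein-level manifold exists. Patients
additionally receive an activation drift of 0.4 on the meanlog scale along
that axis — every drifted marker moves toward its next-stage profile; gating
markers are untouched so subset recovery stays intact. Three batches apply
multiplicative factors (1.0 / 1.2 / 0.85) and the first healthy donor spans
all batches as the MFI reference. A configurable fraction (0.4) of patient
DN-Tem cells carries a GZMK⁺-like transitional profile: intermediate
non-gating markers and a forced singleton clone.

Clone sizes mix singleton carriers (probability 0.6 per cell) with a
truncated power-law tail (exponent 2.5) on sizes ≥ 2, always summing exactly
to the cell count. Outcomes derive from each donor's *true* quadrant:
PR probability is `plogis(intercept + quadrant log-odds)` with default rates
0.45 (Q4), 0.18 (Q1), 0.10 (Q3), 0.08 (Q2); non-responders split evenly
between SD and PD; DCB follows the 6-month response; progression-free
survival is exponential per quadrant with administrative censoring at 720
days. Expression matrices carry block-structured Poisson programs
(quiescence-like up in healthy, activation- and inflammation-like up in
patients, GZMK/GZMH marking the transitional DN population) over a
subsample of 40 cells per donor — enough for scoring validation without
transcriptome-scale bulk.

Randomness uses one root seed with per-donor substreams derived by a stable
multiplicative hash, so output is bit-identical for a given configuration
regardless of ambient RNG state.

**What passing synthetic tests shows — and what it does not.** Recovery of
configured compositions, effect directions and outcome rates demonstrates
that the estimators are unbiased and correctly wired under the generator's
assumptions: log-normal intensity modes, multiplicative batch effects,
exact composition sampling, independent cells. Real cytometry adds spectral
spillover, autofluorescence, doublets, acquisition drift and non-log-normal
tails; real repertoires add sequencing dropout and chain mispairing; none of
these are modelled, and conclusions about robustness to them cannot be drawn
from this suite.

## Validation design notes

* **Problem sizes.** The parameter-recovery suite runs the full 50 + 50 ×
  5,000-cell cohort once and caches it; trajectory checks use seeded
  subsamples of 3,000–6,000 cells, where the kNN graph is exact rather than
  approximate. These sizes give Monte-Carlo error comfortably inside the
  asserted tolerances (e.g. ±0.03 on a 0.20 composition difference).
* **Exact-test discreteness.** Under a null quadrant model the Fisher
  p-value is uniform only asymptotically: the exact test is discrete and
  conservative, which its own type-I-error property asserts
  (`P(p ≤ 0.05) ≤ 0.05` at 500 donors per quadrant). The
  Kolmogorov–Smirnov uniformity check therefore runs at 1,000 donors per
  group, where the discreteness is negligible at 500 replicates; at small
  n a KS rejection reflects the test's discreteness, not an implementation
  error.
* **Clonality/diversity uncoupling.** The patient-versus-healthy scenario is
  paired: the patient repertoire is the same base repertoire plus ~400
  barely expanded clones and five heavily expanded clones of 100 cells.
  With independently drawn bases, the power-law tail makes the baseline
  clonality itself so variable that the shift's sign is seed luck; with a
  singleton-only addition, added evenness outweighs a single expanded clone
  and clonality *falls*. The paired, oligoclonal construction reflects the
  described patient pattern and is sign-stable across seeds.
* **Degenerate inputs.** Empty size vectors, single-clonotype repertoires,
  constant markers, empty quadrants, zero-margin tables, donors missing
  from a cluster and unreachable graph cells all have documented, tested
  behaviours (error, convention value, or flagged missing — never silent
  zeros).

## Known limitations

* Gates are data-driven mixtures, not expert gates; on strongly overlapping
  populations the posterior-0.5 cutoff is a modelling choice, and the
  quantile fallback is cruder still.
* The pseudotime is a graph geodesic, not a fitted principal curve; it
  preserves ordering on monotone manifolds but its absolute values have no
  physical unit, and branch structure is out of scope.
* GSC clustering is a stated substitute for an unpublished categorisation;
  assignments should be read as correlation structure, not as the original
  four groups.
* The outcome model is deliberately minimal (logistic PR, exponential PFS,
  administrative censoring); it supports estimator validation, not clinical
  simulation.
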