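---
title: "Models and methods behind crekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

crekit implements a comparative-epigenomics workflow for two (or an
ordered series of) cell lineages: differential candidate regulatory
elements from ChIP-seq counts, super-enhancer calling and master-TF
nomination, core-regulatory-circuitry cliques from motif scanning in open
chromatin, enhancer–promoter assignment from HiChIP loops, and bivalent
promoter classification. This vignette explains each model, the tunable
parameters and their defaults, the numerical decisions taken where the
design was genuinely open, and what the synthetic-data generators do and
do not emulate.

## Coordinates and interval semantics

All interval tables are 0-based half-open, exactly as in BED; two
intervals overlap when they share at least one base, so adjacent
intervals (`end == start`) do not overlap. GenomicRanges provides the
overlap engine internally (coordinates shifted by +1 at the boundary);
user-facing tables never leave BED convention. Sorting is lexicographic
in chromosome, then start, then end. Anchors are unstranded except where
promoter logic requires strand (promoter windows, profile orientation).

A fragment overlapping k union peaks increments all k counts. This keeps
per-peak counting local and independent, which is what a per-peak count
matrix assumes; the alternative (fractional or unique assignment) couples
neighboring peaks and was rejected. Fragment pairs are expected to be
deduplicated upstream and are counted once.

## The differential-CRE test

The union peak set merges all samples' peak calls transitively at ≥ 1 bp
overlap. Counts are normalized by library size: column j is scaled by
(mean total)/(total_j), preserving within-column ratios and the overall
count scale.

The test models counts as negative binomial with Var(K) = μ + αμ².
Per-peak dispersion is estimated by moments from the pooled within-group
variance, then shrunk toward a trend α(μ) = a₀ + a₁/μ fitted to
mean-binned dispersion averages (20 quantile bins). The shrinkage weight
`shrink_weight` defaults to 0.5 — an even compromise between the noisy
per-peak estimate (8 residual df at n = 5 + 5) and the stable but
locally biased trend; it is a user-visible argument. The Wald statistic
is the log₂ ratio of group means (pseudo-count 0.5) over its delta-method
standard error computed from the shrunk dispersion.

Referring that statistic to a standard normal leaves a small but real
tail inflation: the shrunk variance estimate still carries sampling
noise, so the statistic is t-like, not normal. We therefore use a t
reference with effective degrees of freedom
(n_A + n_B − 2)/(1 − w)², the moderated-t device: shrinkage with weight w
reduces the variance of the variance estimator by (1 − w)², which is
equivalent to multiplying the degrees of freedom by 1/(1 − w)². The
acceptance suite verifies the result: the null fraction of p < 0.05 sits
within 0.05 ± 0.01 on every seed of the reference simulation.

Enrichment calls apply strict inequalities exactly as printed in the
presets (`cre_preset()`): H3K27ac p_adj < 0.001 and |log₂FC| > 3, FOXA1
p_adj < 0.001 and |log₂FC| > 2, H3K27me3 p_adj < 0.01 and |log₂FC| > 1.
A peak at log₂FC = 2.9 with p_adj = 10⁻⁹ is *not called* under the
H3K27ac preset.

### Quantile normalization and where it sits

`quantile_normalize()` maps every column onto the reference distribution
given by the row means of the column-sorted matrix. Ties receive the mean
of the reference values over their rank range, so tied entries share one
value; on tie-free matrices each column's sorted values equal the
reference exactly (verified to 10⁻¹², and cross-checked against
limma::normalizeQuantiles in the tie-free regime). Note the two
guarantees are mutually exclusive on tied data: averaging a tie range
changes the column's value multiset, so "identical sorted columns" can
only hold without ties.

Quantile normalization is rank-preserving but not effect-size-preserving.
When a noticeable fraction of peaks carries strong one-sided effects (the
reference simulation plants 5% of peaks at 16-fold), forcing all columns
onto a common distribution blends the affected and unaffected tails and
attenuates the very fold-changes being tested — on the reference
simulation the median planted |log₂FC| drops from ≈ 3.8 to ≈ 3.2, below
the H3K27ac call threshold. On real matrices with ~10⁵ peaks the same
attenuation is much smaller, which is why published pipelines can apply
QN before differential testing without visible cost. crekit therefore
keeps QN as a first-class optional step (`quantile = TRUE` in
`run_pipeline()`), while parameter-recovery runs use library-size
normalization alone, where fold-changes retain their scale.

### Multi-state comparisons

For an ordered series of states, consecutive pairs are tested at
|log₂FC| > 2 and p_adj < 0.001, and *shared* peaks are those called in at
least one sample of every state and significant in no pairwise
comparison. Presence is an input (a peaks × states logical matrix)
because it derives from per-sample peak calling, which is upstream of
this package.

## Super-enhancers

Stitching chains peaks whose gaps are ≤ 12.5 kb; peaks within 2.5 kb of a
TSS may join a region but cannot bridge two regions (chains are formed on
TSS-distal peaks, and each TSS-proximal peak then attaches to the nearest
chain within the stitch distance). Both distances are arguments; the
defaults are the values conventionally used by rank-ordering SE callers.

The hockey-stick cutoff: sort region signals ascending, scale rank and
signal to the unit square, and take the signal at the point maximizing
x − y — the point where the slope of the (convex) curve crosses 1, i.e.
the tangent point of a 45° line. Regions strictly above the cutoff are
super-enhancers. An all-equal signal vector is degenerate (the curve is
the diagonal); it yields zero super-enhancers with a warning rather than
an arbitrary cutoff.

Regions are assigned to the gene with the nearest TSS within 500 kb
(distance 0 if the TSS is inside the region; equidistant ties go to the
lexicographically smaller gene id and are logged). The 500 kb cap mirrors
the package's peak-to-gene convention elsewhere. A TF's per-sample rank
is the best rank among its super-enhancers; a TF without one receives
that sample's worst rank + 1 so the rank test stays defined —
exclusion is the configurable alternative, but it biases against TFs with
patchy SE landscapes.

The master-TF test considers only TFs in the top 5% by median rank within
either lineage, then applies a one-sided Mann–Whitney U test per
candidate (better ranks in the focal lineage), BH across candidates,
significance at p_adj ≤ 0.10. The U statistic is #(x > y) + ½#(ties); the
p-value is exact by full enumeration of group allocations whenever
C(n, n_x) ≤ 20,000 — exact *including ties*, which matters because rank
tables tie frequently — and a tie-corrected, continuity-corrected normal
approximation beyond.

## Core regulatory circuitry

PWM scanning computes log₂-odds against a background base composition
(default uniform) at every offset on both strands; the default hit
threshold is 70% of the PWM's maximum achievable score (an absolute
`min_score` override exists for degenerate PWMs whose maximum is 0).
Offsets containing N are skipped and counted in a log message. Planted
probability 0.91 consensus PWMs of length 10 have a maximum score of
≈ 18.6 bits, putting the default threshold at ≈ 13 bits — background
hits at that score are vanishingly rare in uniform sequence.

The regulatory graph has an edge A → B when a hit of A's PWM overlaps
open chromatin inside B's super-enhancer; a hit inside the SE but outside
ATAC peaks does not count, which is the package's encoding of
"restrict the motif search to open chromatin". Candidate clique members
must be auto-regulated (a self-edge); the support graph joins A and B
only when both directions exist; cliques are maximal cliques of size ≥ 2,
enumerated by igraph and returned in deterministic sorted order. The
clique enrichment score divides a TF's clique count by the total number
of cliques, all cliques weighted equally — weighting by clique size is a
conceivable alternative but changes the score's interpretation as a
membership fraction. CES clustering keeps TFs with nonzero CES in at
least ⌈0.8 · n⌉ samples of some lineage and uses Canberra distance with
ward.D2 linkage; pairs of all-zero profiles, whose Canberra terms are all
0/0, are assigned distance 0.

"Expressed" TFs are those whose mean signal over the gene body plus 5 kb
of promoter exceeds the median over all genes — a deliberately simple,
scale-free criterion exposed as `expressed_genes()`; any external
expressed set can be passed instead.

Motif coverage of an SE set is the union-merged hit length divided by the
summed SE length, so overlapping hits count once.

## Loops

Loops are filtered to cis records with anchor-midpoint spans in
[5 kb, 3 Mb] and anchor order normalized. The promoter window is the
5 kb strictly upstream of the TSS, half-open and strand-reflected:
[TSS − 5000, TSS) on +, [TSS + 1, TSS + 5001) on −. The TSS base itself
is excluded — "upstream" is read strictly; including it would add a
single base and no observed loop assignment can depend on it at 5 kb
anchor resolution. A gene links to a peak when some loop has one anchor
on the promoter window and the other on the peak; links are deduplicated
per (gene, peak), so duplicate loop records cannot inflate counts, and
the assignment is symmetric under swapping every loop's anchors. The
association test compares expression log₂ fold-changes of genes with
exactly one looped CRE against genes with two or more (two-sided
Wilcoxon, exact when sizes permit and values are tie-free; significance
at p < 0.01).

## Bivalent promoters

The EM fit of the two-component Gaussian mixture is deterministic: data
are split at the median, each half initializes one component, and
components are relabeled so μ_low ≤ μ_high. Convergence at log-likelihood
gain < 10⁻⁸ or 1000 iterations; σ collapsing to ~0 or an emptying
component raises an error rather than returning a degenerate fit. The
procedure is two-stage by construction: H3K4me3 is fit on all promoters,
the K4 cutoff μ_high − 4σ_high is applied, and H3K27me3 is fit only on
K4-high promoters with cutoff μ_low + 4σ_low. The ±4σ cutoffs use the
fitted component σ alone, without weighting by mixture proportions.
Quadrants: K4-high ∧ K27-high = bivalent, K4-high only = active,
K27-high only = repressed, neither = unmarked; the four quadrants
partition all genes.

The enrichment test crosses bivalent versus the two K4-low quadrants
(unmarked + repressed) with membership in the upregulated set (log₂FC > 3
and p_adj < 10⁻⁶ by default), Pearson chi-squared without continuity
correction — the continuity correction is a small-sample device that
biases conservative at these table sizes and is off by default
(configurable through `stats::chisq.test` semantics).

## The synthetic-data generators

Each generator is a pure function of its `sim_config()` (seed included)
and writes standard formats that round-trip through the package readers.
The defaults define the reference simulation:

* **Counts**: 5,000 peaks, 5 + 5 samples, NB with baseline mean 50
  fragments/peak (log-normal across peaks, sd(log) = 0.7), dispersion
  α = 0.1, library factors log-normal(0, 0.25) — modest realistic depth
  variation; 250 planted effects at |log₂FC| = 4 alternating in
  direction.
* **SE landscape**: 500 background 1 kb peaks 20 kb apart (never stitch)
  with signal 0.5 + Exp(rate 2), plus five clusters of five 1 kb peaks
  with 2 kb gaps (well under the stitch distance) at 200 + Exp(mean 50)
  signal each. The separation is chosen from the tangent geometry: the
  cutoff stays above the background tail iff every background
  order-statistic gap is below s_max/n ≈ 2.5, and for Exp(rate 2) the
  probability of any gap exceeding that is below 1%, so the planted
  elbow is recoverable by construction.
* **Motif genome**: uniform ACGT background (GC ≈ 0.5), one SE per
  planted TF containing two ATAC peaks, all planted TFs' consensus sites
  written into each TF's first ATAC peak — one fully reciprocal,
  auto-regulated clique — and one PWM left unplanted as a negative
  control.
* **Loops**: 60 genes, k ∈ 0..5 looped CREs each (all bins populated),
  expression log₂FC = k · `loop_gene_effect` + N(0, 0.5); anchors are
  5 kb bins over the promoter window and the CRE.
* **Promoter marks**: 10,000 genes; K4 components N(2, 1)/N(8, 1)
  (separation 6σ, weight_high 0.55), K27 components N(1, 0.5)/N(4, 0.5)
  (separation 6σ, weight_high 0.3); quadrant truth from the generating
  components; upregulation planted at rate 0.3 in bivalent versus 0.05
  elsewhere so the enrichment test has a true signal.

What the generators do **not** emulate: GC-dependent coverage bias,
fragment-length structure, copy-number artifacts, correlated replicates,
realistic genome composition or repeat content, distance-dependent
contact frequency, and mixture tails heavier than Gaussian. Passing
recovery tests therefore demonstrates the correctness and calibration of
the algorithms under their stated models, not robustness to every
artifact of real libraries.

## Problem sizes and runtime

The reference sizes (5,000 peaks × 10 samples; 500-peak landscapes;
10,000 promoters; 60 loop genes; a 120 kb motif genome) were chosen so
the complete synthetic pipeline (`run_pipeline()`) finishes in well under
two minutes on a single CPU while leaving every statistical check
well-powered; all sizes are `sim_config()` fields.

## Known limitations

* The differential test supports two-group and ordered multi-state
  designs only; no covariates or batch terms (limma/DESeq2 are the tools
  of choice there).
* Loop significance modeling is upstream: `load_loops()` filters on a
  provided q-value but does not recompute contact-frequency backgrounds.
* Signal input is bedGraph; bigwig files must be converted externally.
* The promoter-state model is two 1-D mixtures with a quadrant rule, not
  a joint 2-D mixture; genes near both cutoffs are classified hard, with
  no posterior uncertainty reported.
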