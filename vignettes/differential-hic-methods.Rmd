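---
title: "Methods: differential Hi-C analysis with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential Hi-C analysis with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadfuse)
```

# Scope and rationale

`tadfuse` compares the three-dimensional genome organization of two cell
states from cis Hi-C contact matrices: distance decay, A/B compartments,
TADs, cross-condition TAD fusions, and the placement of differentially
expressed genes (DEGs) relative to those structures. It targets the
situation where the primary data (patient Hi-C, scRNA-seq DEG lists) are
not publicly deposited: a generative model with planted structure stands
in for the data, so every stage of the analysis can be validated by
parameter recovery rather than by comparison to an unavailable dataset.

All coordinates are 0-based half-open in files; bin indices inside R are
1-based. Only within-chromosome (cis) contacts are modelled; the
whole-genome view is a block-diagonal mosaic.

# The generative model

For a genome with uniform bins, condition-specific architecture is drawn
first: each chromosome is partitioned into `n_tads_per_chrom` contiguous
TADs (sizes: a minimum of `min_tad_size` bins plus a multinomial split of
the remainder), and compartment labels alternate in blocks of
`compartment_block_len` bins with random phase and starting label. The
expected contact count between bins `i != j` of one chromosome is

```
lambda_ij = K * |i-j|^(-alpha)
              * (1 + delta_c * [same compartment])
              * (1 + delta_t * [same TAD])
              * (1 + bb_boost * [both B])
```

with `K` fixed per chromosome so the expectations sum to the chromosome's
share of the target depth (shares proportional to bin-pair counts).
Observed counts are independent Poisson draws on the upper triangle,
mirrored; the diagonal is never simulated (self-ligation artifacts are not
analysed). Poisson noise was chosen over negative binomial deliberately:
it is the simplest model consistent with count data, and an overdispersion
knob is out of scope.

The transformed condition is derived from the baseline by removing
`n_fusions` randomly chosen interior boundaries (recorded as fusion
events), flipping `n_switches` random bin labels (recorded with
direction), raising the TAD contrast to `delta_t / (1 - attenuation)`
(TAD compaction), steepening the decay exponent by `decay_shift`
(proximal contacts gain at the expense of distal ones after
normalization), and boosting B-B pair intensity by `1 + bb_boost`
(strengthened inactive-compartment interactions). The last two knobs are
deliberately separate from the boundary/label edits: they reproduce the
matrix-scale and compartment-scale signatures of a transformation while
fusions and switches carry the TAD-scale and switch-scale ones.

An orientation track — the planted compartment indicator plus Gaussian
noise (sd 0.3 by default) — stands in for the GC-content or gene-density
track that fixes the eigenvector sign on real data.

The DEG simulator places down-regulated genes uniformly over bins and
up-regulated genes with sampling odds `omega >= 1` for bins strictly
inside fused TADs, draws adjusted p below 0.05 for every listed gene, and
records each gene's true structural category.

## Default study conditions

The default configuration simulates three 20 Mb chromosomes at 100 kb
resolution (600 bins) with ~1 Mb TADs (20 per chromosome) nested inside
~3 Mb compartment blocks, `alpha = 1`, `delta_c = 0.6`, `delta_t = 1`, and
1e7 expected cis contacts per condition; the derived condition uses 4
fusions, 20 switches, 30% attenuation, `decay_shift = 0.15` and
`bb_boost = 0.3`, and the DEG table has 2000 genes, half up-regulated,
with planted odds 5. The compartment-block length deliberately exceeds the
TAD size: in real genomes compartment domains span several TADs, and when
the hierarchy is inverted (blocks smaller than TADs) compartment edges
fall so close to TAD boundaries that boundary identities become ambiguous
between conditions. The 100 kb working resolution and the 1 Mb coarse
overview match common practice for compartment/TAD analysis and
whole-genome heatmaps respectively. Recovery experiments use a single
500-bin (50 Mb) chromosome; these problem sizes keep a full run of the
test suite and acceptance script in the seconds-to-minutes range while
leaving per-pair counts (~150 at depth 1e7) high enough that recovery is
limited by the method, not the sample size.

## What the generator does not emulate

Trans contacts, read-level artifacts (mappability, restriction-fragment
geometry), copy-number variation, overdispersed noise, nested/hierarchical
TADs and loops are all absent. Passing recovery tests therefore shows the
estimators are correct under the stated model, not that they are robust to
every artifact of patient material.

# Analysis methods and numerical choices

**Balancing.** ICE iterative correction; no published normalization method
was prescribed for this analysis, and ICE is the field standard with an
explicit bias vector. Bins with zero marginal, or marginal below the 2nd
percentile of nonzero marginals, are masked before iteration — at desk
scale a handful of weak bins otherwise dominates the correction.
Convergence: maximum relative row-sum deviation below `tol = 1e-5`, at
most 200 iterations (non-convergence is a flagged warning, not an error).
Balanced values are scaled to mean unmasked row sum 1.

**Expected values and O/E.** Per-chromosome mean over unmasked pairs at
each separation (`d = 0` excluded); O/E entries at separations with no
valid pair are missing, masked rows/columns are missing.

**P(s) and crossover.** Pairs are pooled genome-wide, converted to
probabilities (total cis sum 1), and reduced per log-spaced distance bin
(8 per decade) by the geometric mean of the positive probabilities;
zero-count pairs are excluded from the geometric mean rather than
collapsing the bin to zero. The crossover is the first sign change of
`log2(P_2/P_1)`, linearly interpolated in log10 distance; identical curves
have none.

**Compartment eigenvector.** Per chromosome, the Pearson correlation
matrix of unmasked O/E rows (diagonal excluded; zero-variance rows
dropped) is eigendecomposed. Among the three leading eigenvectors the one
most correlated in absolute value with the orientation track is taken:
at weak compartment contrast the very first eigenvector can track residual
distance/edge structure instead of the checkerboard, and selecting by
orientation correlation (standard practice in compartment callers)
restores monotone strength recovery; at the default contrast the choice
coincides with the leading eigenvector. E1 is sign-oriented by the track,
scaled to unit variance per chromosome; `E1 = 0` and masked bins are `NA`
and excluded from saddles and switches. Chromosomes with fewer than 10
unmasked bins get an all-`NA` track with a warning.

**Saddle and strengths.** Genome-wide equal-occupancy E1 quantiles
(`Q = 20`, extreme 2% of E1 trimmed per tail; group 1 = strongest B), mean
O/E per group pair accumulated over both orderings so the saddle is
symmetric by construction. Corner blocks of `ceiling(Q * 0.2)` groups give
AA/BB/AB strengths; single-group corners are noticeably noisier, which is
why the default corner fraction averages four groups.

**Insulation and boundaries.** The diamond at bin `i` spans rows
`i-w .. i-1` against columns `i .. i+w-1` — the half-open window centred
on the junction at the bin's left edge — so a boundary between bins
`i-1` and `i` yields its minimum exactly at `i`, with no two-bin plateau
tie to break. (A window that excludes bin `i` on both sides produces a
systematic one-bin offset between the called minimum and the junction.)
The track is `log2(raw / chromosomal geometric mean)`; the geometric mean
is robust to heavy-tailed rows. Boundary strength is the mean elevation of
the two flanking `ceiling(w/2)`-bin windows of the track above the bin's
own value. Boundaries are local minima with strength at least 0.1,
compared against nearest *defined* neighbours so an isolated masked bin
cannot hide a minimum; plateaus resolve to their leftmost bin; edge bins
(track undefined within `w` of a chromosome end) are never called.
Defaults: `w = 5` bins (500 kb at 100 kb resolution).

**Segmentation.** Boundaries plus chromosome ends tile each chromosome;
intervals shorter than `min_tad = 3` bins are merged by dropping the
flanking boundary with the weaker insulation dip (the left one when no
track is supplied). Tiling is asserted on every output.

**Intra/inter ratio.** Intra is the mean balanced value over unmasked
within-TAD pairs; inter over pairs spanning *adjacent* TADs at separations
no larger than the longest TAD, so the two averages cover comparable
distances. A zero inter mean is reported as a missing ratio with a flag.
Condition comparisons use a shared (condition-1) segmentation so the
ratio change reflects contacts, not segmentation drift.

**Aggregate TADs.** Each TAD of at least 3 bins, with a half-TAD flank on
each side (TADs whose flank would cross a chromosome end are skipped), is
rescaled to 30x30 by bilinear interpolation and averaged; missing entries
are excluded cellwise and the result symmetrized.

**Fusion detection.** A condition-2 TAD is a fusion if both endpoints
match a condition-1 boundary or chromosome end within `tol = 1` bin and it
contains a condition-1 boundary with no condition-2 boundary within
`tol`; one event is emitted per lost boundary. A boundary that merely
shifts by more than `tol` breaks the endpoint match and is (correctly) not
a fusion. The pipeline additionally corroborates events by the physical
signature of fusion — an insulation rise of at least 0.25 at the lost
boundary, half the `log2(1/(1-0.3)) ~ 0.51` rise expected from the default
attenuation alone — which suppresses events caused by a called boundary
wobbling beyond `tol` while the boundary itself persists. The filter is
off by default in `detect_fusions()` itself.

**DEG integration.** Gene position is the TSS (assigned to the unique
half-open bin containing it); whole-gene-body overlap was rejected to keep
the three categories an exact partition. The boundary set is the union
over both conditions' boundaries with a ±1-bin flank — no single condition
is privileged, since which condition's boundaries define "at a boundary"
is a modelling choice; condition 1 is fixed as the baseline (CLL-like)
state throughout. Boundary takes precedence over merged_tad, and fused
intervals exclude their two terminal bins, so the partition is total and
unambiguous. Genes with adjusted p >= 0.05 are dropped with a logged
count. Enrichment per direction-by-category table: odds ratio with
Haldane 0.5 correction when a cell is zero, upper-tail hypergeometric p,
and Benjamini-Hochberg q across the four emitted tables only (a small,
explicitly stated family).

**Differential matrices.** Log2 ratio (not subtraction) of
depth-normalized balanced maps, with a shared pseudocount of `1e-6` times
the mean unmasked entry; sharing the pseudocount makes the differential
exactly antisymmetric under argument swap. Coarsening to the 1 Mb overview
sums counts in blocks, pooling remainder bins into the last coarse bin
(recorded in metadata) instead of erroring.

# Determinism

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; the pipeline derives per-stage seeds from a single run
seed and the stage name. Two runs with the same configuration and seed
produce byte-identical outputs, including the JSON run report.

# Known limitations

- Compartment transitions insulate: in the generative model (and in real
  genomes) a compartment edge produces an insulation dip, so boundary
  calls include compartment-block edges alongside planted TAD boundaries.
  Boundary precision/recall is therefore assessed with the compartment
  contrast switched off; on full simulations the extra boundaries are
  genuine structure, not false positives, but they do inflate the
  boundary-flank share of the genome.
- Compartment switches move compartment edges, occasionally producing
  boundary-loss events that are not planted TAD fusions; the insulation
  corroboration filter removes most but not necessarily all of them.
- Fractions such as "DEGs at TAD boundaries" depend strongly on boundary
  density and flank width and are not comparable across genomes of
  different structure or resolution.
- The hypergeometric enrichment test treats gene placements as
  exchangeable; clustering of genes within bins (many genes per bin) would
  make it anticonservative on real annotations.
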