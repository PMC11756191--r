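# tadfuse

Two-condition comparison of Hi-C contact maps at matrix, compartment and
TAD scale, with integration of differential-expression gene lists into the
structural annotations. The package is built for desk-scale studies of
global chromatin reorganization between two cell states — the motivating
setting is the transformation of chronic lymphocytic leukaemia (CLL) into
diffuse large B-cell lymphoma (Richter syndrome), where the transformed
cells show enhanced proximal and weakened distal contacts, strengthened
B-compartment interactions, compacted TADs and TAD fusions that harbour
upregulated genes.

Because patient Hi-C and scRNA-seq data for such studies are rarely
deposited, the package ships a synthetic-data generator with fully known
planted structure, so that every analysis stage is testable end to end and
every recovery claim is checked against ground truth.

## What it computes

**Matrix scale.** Raw cis contact maps (cooler-style bins+pixels text
tables) are balanced by iterative correction (ICE): each chromosome block
`W` is repeatedly divided by the outer product of its relative marginals
until row sums equalize, yielding bias vector `b` with
`W_ij^bal = W_ij / (b_i b_j)`. Contact probability versus separation,
`P(s)`, is the geometric mean of per-pair contact probabilities in
log-spaced distance bins; for two conditions the crossover distance is the
separation where `log2(P_2(s)/P_1(s))` changes sign. A coarse (1 Mb)
differential map is the entrywise `log2((A+eps)/(B+eps))` of the
depth-normalized balanced maps.

**Compartment scale.** The compartment eigenvector E1 is taken per
chromosome from the Pearson correlation matrix of the O/E
(observed-over-expected) rows, sign-oriented by an orientation track (GC
content / gene density, or the synthetic compartment indicator); bins with
`E1 > 0` are A, `E1 < 0` are B. Per-bin changes between conditions are
classified StableAA / StableBB / SwitchAB / SwitchBA. Saddle plots average
O/E over E1-quantile pairs; corner means give AA, BB and AB strengths and
the compartmentalization score `log2(AA*BB/AB^2)`.

**TAD scale.** The insulation score at bin `i` is the mean balanced
contact in a `w x w` diamond spanning the junction at the bin's left edge,
log2-normalized to the chromosomal geometric mean; boundaries are local
minima with sufficient prominence; TADs tile each chromosome between
boundaries. Cross-condition TAD fusions are condition-2 TADs whose
endpoints match condition-1 boundaries but which swallowed at least one
condition-1 boundary (optionally corroborated by an insulation rise at the
lost boundary). Intra- vs inter-TAD contact ratios and aggregate TAD
(average rescaled domain) matrices quantify TAD compaction.

**Integration.** Significant genes are mapped by TSS to bins and
classified as `boundary` (within a flank of any TAD boundary of either
condition), `merged_tad` (inside a fused-TAD interior) or `other`; the
package reports the boundary fractions for all/up/down genes, the
`UPG^TAD` / `DWG^TAD` gene sets, and direction-by-category enrichment
(odds ratio with Haldane correction, hypergeometric p, BH q).

## Worked example

The `analysis/` scripts run the whole study over the default synthetic
configuration (three 20 Mb chromosomes at 100 kb resolution, ~1 Mb TADs
inside ~3 Mb compartment blocks, 1e7 cis contacts per condition; the
derived condition plants 4 TAD fusions, 20 compartment switches, 30%
insulation attenuation, a steeper distance decay and boosted B-B
contacts):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_matrix_overview.R
Rscript analysis/03_compartments.R
Rscript analysis/04_tads_fusions.R
Rscript analysis/05_integration.R
```

which prints, stage by stage:

```
planted: 57 TAD boundaries, 4 fusions, 20 switches, 2000 DEGs (omega=5)
P(s) crossover at 0.30 Mb; condition 2 higher below it: TRUE
switch categories: StableAA 302, StableBB 267, SwitchAB 8, SwitchBA 5
strengths condition 1: AA 1.200 BB 1.172 AB 0.790 overall 1.171
strengths condition 2: AA 1.240 BB 1.287 AB 0.720 overall 1.622
BB strength change (cond2 - cond1): +0.115
intra/inter contact ratio: 5.59 -> 6.93 (fold 1.24)
fusions: 4 detected, 4 planted, recall 1.00, precision 1.00
mean insulation change at lost boundaries: +0.683
DEGs at TAD boundaries: 30.4% of all, 29.0% of up, 31.9% of down
genes inside merged TADs: 257 up (UPG^TAD), 59 down (DWG^TAD)
UPG^TAD enrichment: OR 5.52 [4.09, 7.44], q = 2.3e-35
```

Reading the output: the transformed condition gains proximal at the
expense of distal contacts (a finite P(s) crossover with condition 2
higher below it), strengthens B-B compartment interactions (+0.115),
compacts TADs (intra/inter ratio fold 1.24; insulation rises by +0.68 at
fused boundaries), and all four planted fusions are recovered with no
false positives. The upregulated genes placed inside fused TADs with
planted odds 5 are recovered with an odds ratio of 5.52 whose confidence
interval covers the truth. Tables and tracks land under `results/`.

The same chain is available as one call:

```r
library(tadfuse)
report <- run_pipeline(default_config(), outdir = "results/run", seed = 1)
```

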