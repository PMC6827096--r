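---
title: "Multi-breed genomic prediction with block-resampled genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-breed genomic prediction with block-resampled genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genomic selection needs a large phenotyped, genotyped reference
population, which small indigenous breeds (often a few dozen sampled
animals each) do not have. A natural question is whether several related
breeds can be pooled into one reference, and how much accuracy that buys
or costs relative to within-breed evaluation. `mosaicgp` provides a
simulation laboratory for that question: it builds a structured
multi-breed genotype panel with realistic linkage disequilibrium (LD),
expands it to population scale while preserving each breed's LD and
allele frequencies, simulates quantitative traits under a range of
genetic architectures, and evaluates GBLUP prediction accuracy under
single-breed, multi-breed and pooled reference designs.

## The simulation pipeline

### Founder genotypes

Real panels of this kind are rarely redistributable, so the package
starts from a forward-in-time founder simulator
(`generate_founders()`). One ancestral random-mating population (default
effective size 200, 100 generations, initial allele frequencies uniform
on 0.05–0.95) recombines with Poisson crossovers on the genetic map;
it splits into 3 groups (Ne 100, 50 generations by default) and each
group splits into breeds (4+3+3 breeds, Ne 50, 30 generations). From
each breed's final generation, 21–26 founders are sampled (25 per breed
in the study configuration). Drift along this three-level history
produces hierarchical differentiation: breeds cluster into their groups
on principal components, and cross-group FST exceeds within-group FST.

Two defaults deserve comment:

* **Marker spacing.** 20,000 markers on 10 chromosomes with
  exponentially distributed gaps of mean 4 kb. A Poisson marker process,
  rather than an exactly regular 4 kb grid, is what populates the
  short-distance (0–2.5 kb) LD bins used by the phase-persistence
  diagnostics; it also resembles real array spacing.
* **Recombination rate.** 80 cM/Mb, deliberately far above the ~1 cM/Mb
  cattle average. The simulated genome is only ~80 Mb; at realistic
  rates its total map length would be ~1 Morgan and a handful of
  effective chromosome segments would make GBLUP unrealistically
  accurate. Inflating the map restores a genome-wide effective segment
  number (Me on the order of 10^3) that places prediction accuracies in
  the regime reported for real cattle data. This is a deliberate
  desk-scale calibration, chosen once, exposed in `founder_config()`.
  The split-generation counts shape between-breed sharing: the group
  phase (50 generations at Ne 100) separates the groups, while the short
  breed-split phase (30 generations at Ne 50) leaves breeds within a
  group sharing enough LD that a within-group reference outperforms a
  cross-group one.

### Block-resampling expansion

`expand_breed()` implements the core genotype simulator: each simulated
individual is a mosaic of founder haplotype segments. Markers are
partitioned into consecutive blocks of 500 within each chromosome, and
for every simulated gamete and block independently one segment is drawn
uniformly, with replacement, from the breed's `2 x n_founders` haplotype
pool. Within blocks this reproduces the founders' haplotype (and hence
LD and allele-frequency) distribution exactly in expectation; across
block boundaries segments are independent, which mimics LD broken at
strong recombination hotspots. Resampling is done at the haplotype
level — the only reading that preserves Hardy–Weinberg proportions and
phase statistics in the expanded panel — so founders must be phased
(synthetic founders are generated phased; user data must arrive
phased). Blocks are fixed from each chromosome's start; no mutation, no
within-block recombination, no pedigree.

### Traits

`sample_qtl()` draws QTL positions uniformly among polymorphic markers
of the pooled panel, so QTL segregate in all breeds with breed-specific
frequencies. Effects are Normal with class variances 0.0001 / 0.001 /
0.01 (small / medium / large) times a nominal scale variance of 1. Four
preset architectures span 100 all-large QTL to 10,000 all-small QTL.
True breeding values are `TBV_i = sum_j x_ij a_j` with dosage coding
0/1/2.

The nominal effect-scale variance is *not* the genetic variance the QTL
create; that depends on allele frequencies. `simulate_phenotypes()`
therefore scales environmental noise by the *realized* genetic
variance: `var(env) = Vg (1 - h2) / h2`. In a strongly structured
panel the pooled `var(TBV)` contains a large between-breed component;
scaling by it would silently deflate the within-breed heritability that
genomic prediction actually operates on. When breed labels are passed
(`groups =`), `Vg` is the mean within-breed variance of TBV, so each
breed's trait has (in expectation) the target heritability. The study
driver uses this group-wise scaling; without `groups` the pooled
variance is used.

## The model

GBLUP (`gblup()`) fits `y = Xb + g + e` on the reference individuals,
with `g ~ N(0, G sigma_g^2)` and `e ~ N(0, I sigma_e^2)`. The genomic
relationship matrix (`compute_grm()`) follows the Yang et al. form:
off-diagonals `(1/N) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2p_i(1-p_i))`,
diagonals `1 + (1/N) sum_i (x_ij^2 - (1+2p_i)x_ij + 2p_i^2) /
(2p_i(1-p_i))`, with allele frequencies taken from the pooled analysis
sample (reference plus validation) by default. With `lambda =
sigma_e^2 / sigma_g^2`, fixed effects are estimated by GLS and breeding
values by `g_hat = G_{.r} (G_rr + lambda I)^{-1} (y - X b_hat)`;
validation individuals are predicted by the same genomic regression.
Fixed effects are an overall mean, plus breed for multi-breed
references.

Choices worth noting:

* **No pedigree polygenic term.** Resampled individuals have no
  pedigree, so the model contains a single genomic random effect; any
  residual polygenic variance is absorbed by `g` and `e`.
* **lambda from the true simulated heritability** by default: the
  simulation controls h2, and using the true ratio removes
  variance-component estimation noise from the design comparison.
  EM-REML (`estimate_variances_reml()`) is available when lambda must be
  estimated; it eigendecomposes the GRM once, iterates to relative
  tolerance 1e-6 (cap 200 iterations, warning on non-convergence), and
  returns non-negative components.
* **Ridge.** Block-resampled individuals can be near-duplicates, so
  `1e-6 * mean(diag(G))` is added to the GRM diagonal. The ridge is
  applied to the whole GRM (conceptually `G + eps I`), which keeps the
  two-step solver algebraically identical to the joint mixed-model
  equations on the ridged GRM — a property the test suite checks against
  a dense MME oracle at 1e-8.
* **Markers for the GRM** are those polymorphic in the analysis sample;
  QTL markers are retained (the package can exclude them by passing a
  reduced marker set to `compute_grm()`, but retention is the default).

## Reference designs and accuracy

`scenario_spec()` / `run_grid()` evaluate: within-breed (1,200
reference / 300 held-out validation per breed), across-breed (a foreign
single-breed reference, 300 random validation individuals per other
breed), combined (120 from each of 10 breeds), and three-breed
references (400 each) composed either within one K-means group or with
one breed per group. Groups are recovered from the data by PCA of
founder dosages and K-means on breed centroids in the top 5 PCs
(`kmeans_groups()`), not read from the generator's configuration.
Accuracy is the Pearson correlation between predicted and true breeding
values within each validation breed; summaries average over validation
breeds within a replicate, then over replicates. Splits are drawn once
per design; replicates share genotypes and redraw QTL and phenotypes,
so the GRM and its Cholesky factor are reused across the whole
strategy-by-heritability grid of a design.

`phase_persistence()` quantifies how faithfully an expansion preserves
its founders' LD: for every same-chromosome marker pair in a distance
bin (2.5 kb steps to 10 kb, 10 kb steps to 100 kb, 100 kb steps to
1 Mb), the signed haplotype correlation r is computed in both panels and
the bin's statistic is the Pearson correlation of paired r values.
Signed r (not r^2) is used because persistence of the *sign* of linkage
phase is what matters for sharing marker effects across populations; a
dosage-based composite-LD variant is available behind a flag. Pairs
monomorphic in either panel are skipped; empty bins are reported as
missing, never zero.

## Problem sizes and determinism

The shipped study configuration (`run_study()` with
`study_founder_config()`) uses 10 breeds x 25 founders, 1,500 simulated
individuals per breed, 10 trait replicates per cell, and the full
4-strategy x 3-heritability grid within breeds. Marker generation is
oversized (26,500 markers at ~3 kb gaps) because roughly a quarter of
markers drift to monomorphism across founders and are dropped; the
analysed panel then carries ~20,000 SNPs at ~4 kb mean spacing. On one CPU core this takes on the order of ten
minutes; the dominant costs are the founder simulation (compiled
meiosis loop) and one GRM per reference design. All randomness flows
from one master seed through deterministically spawned child seeds;
rerunning with the same seed reproduces every accuracy bit for bit.

## What the synthetic panel does and does not emulate

It emulates: hierarchical breed structure with within-group breeds more
similar than cross-group ones; LD decaying over hundreds of kb;
breed-specific allele frequencies at shared QTL; small founder pools
per breed. It does not emulate: mutation, selection, migration,
non-random mating, sex chromosomes, array ascertainment bias, genotyping
error, or real cattle demography — so passing tests show the *methods*
behave correctly under a realistic structure, not that any particular
real-data accuracy would be attained.

Two desk-scale distortions matter when comparing with full-genome
studies. First, with ~15,000 markers the causal variants are a
non-negligible fraction of the panel, so a little accuracy transfers
across even unrelated populations through the shared QTL themselves
(their effects are shared by construction); with hundreds of thousands
of markers this direct-transfer channel is far more dilute. Across-breed
accuracies here are therefore expected to sit slightly above a
full-genome equivalent. Second, the inflated recombination rate trades
map realism for a realistic effective segment count, as discussed above.

## Known limitations

* QC operates on dosages; half-called genotypes are treated as missing.
* The PLINK text reader assigns allele codes alphabetically per marker;
  a marker monomorphic for the code-1 allele round-trips with flipped
  orientation (dosage `2 -> 0`), the usual ambiguity of allele-coded
  text formats.
* `estimate_variances_reml()` assumes one genomic variance component;
  no multi-kernel or dominance models.
* K-means grouping operates on breed centroids; it will not detect
  admixed individuals within a breed.
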