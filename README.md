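# mosaicgp

Simulation toolkit for **multi-breed genomic prediction**: how accurate
is GBLUP for small, structured livestock populations when the reference
population is a single breed, a pool of related breeds, or a pool of
everything?

Small indigenous breeds rarely have enough phenotyped, genotyped animals
to form a reference population on their own. `mosaicgp` builds a
realistic in-silico laboratory for that setting:

1. **Founder simulation** — a forward-in-time drift/recombination model
   generates phased genotypes for 10 breeds (21–26 founders each) with a
   three-level hierarchy (ancestral population → 3 breed groups → 10
   breeds), high marker density and LD decaying over hundreds of kb.
2. **Block-resampling expansion** — each breed is expanded to 1,500
   individuals by resampling founder haplotype segments in blocks of 500
   adjacent markers, preserving the breed's allele frequencies and
   within-block LD (verified by persistence-of-phase diagnostics).
3. **Trait simulation** — QTL drawn from the pooled panel under four
   architectures (100 large-effect QTL up to 10,000 small-effect QTL;
   effect classes N(0, 0.0001), N(0, 0.001), N(0, 0.01)), true breeding
   values `TBV_i = Σ_j x_ij a_j`, phenotypes at heritabilities
   0.1 / 0.3 / 0.6 with environmental variance `Vg (1 − h²) / h²`.
4. **GBLUP evaluation** — mixed model `y = Xb + g + e`,
   `g ~ N(0, G σg²)`, with the Yang et al. genomic relationship matrix
   and `λ = σe²/σg²` from the simulated heritability; prediction accuracy
   is `cor(GEBV, TBV)` in held-out validation animals, per breed.

It also provides genotype QC (call rate, MAF, Hardy–Weinberg), PLINK
.ped/.map import/export, PCA + K-means breed grouping, LD-decay and
persistence-of-phase statistics, and EM-REML variance components.

## Worked example

```r
library(mosaicgp)

# a small panel: 4 breeds in 2 groups, ~3 s
cfg <- founder_config(n_breeds = 4, groups = c(1, 1, 2, 2),
                      founders_per_breed = 20, n_markers = 2000,
                      n_chr = 4, seed = 11)
founders <- generate_founders(cfg)
founders
#> genotype_panel: 80 individuals, 1370 markers, 4 breed(s), 4 chromosome(s)
#> breeds: B01 (20), B02 (20), B03 (20), B04 (20)

# expand one breed and check that LD phase is preserved
sim <- expand_panel(founders, resample_config(n_per_breed = 400, seed = 12))
phase_persistence(founders, subset_panel(sim, which(sim$breed == "B01")),
                  phase_bins()[1:4, ])
#>   lower upper n_pairs correlation
#> 1     0  2500     284   0.8589392
#> 2  2500  5000     280   0.8217325
#> 3  5000  7500     304   0.7845943
#> 4  7500 10000     259   0.7463506

# simulate a trait (100 large-effect QTL, h2 = 0.6) and fit GBLUP
qtl  <- sample_qtl(sim, architecture_strategy("I"), seed = 13)
tbv  <- compute_tbv(sim, qtl)
trait <- simulate_phenotypes(tbv, h2 = 0.6, groups = sim$breed, seed = 14)

b1   <- sim$ids[sim$breed == "B01"]
ref  <- b1[1:300]; val <- b1[301:400]
p1   <- allele_freq(sim, individuals = b1)  # GRM needs polymorphic markers
grm  <- compute_grm(sim, individuals = b1, markers = which(p1 > 0 & p1 < 1))
fit  <- gblup(y ~ 1, data.frame(id = ref, y = trait$y[match(ref, trait$id)]),
              grm, reference = ref, validation = val, h2 = 0.6)
fit
#> GBLUP fit: 300 reference, 100 validation individuals; lambda = 0.6667
#> fixed effects:
#> (Intercept)
#>   -2.148317

accuracy(predict(fit), tbv[val])
#> [1] 0.9052072
```

The phase-persistence correlations (~0.75–0.86) and validation accuracy
(~0.9) reflect the small toy genome: few marker pairs per bin, noisy
founder LD estimates from 40 haplotypes, and a small effective number of
segments. The full study configuration below (20,000 SNPs, 25 founders,
1,500 individuals per breed) puts the shortest-bin phase persistence
above 0.99 and within-breed accuracy in the 0.6–0.7 regime typical of
dense single-breed references.

The full experiment grid of the study — within-breed, across-breed,
combined-10 and three-breed reference designs over four architectures
and three heritabilities — runs with:

```r
study <- run_study(seed = 1, n_replicates = 10, verbose = TRUE)
study$headline   # named list of the headline accuracies
study$summary    # per-design / strategy / h2 means and sds
```

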