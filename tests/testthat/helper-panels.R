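# Small fixture builders used across test files.

# A deterministic panel from an explicit haplotype matrix (2n x m, 0/1/NA).
toy_panel <- function(hap, breed = NULL, chr = 1L, bp = NULL, spacing = 1000) {
  m <- ncol(hap)
  n <- nrow(hap) / 2
  if (is.null(bp)) bp <- seq_len(m) * spacing
  map <- data.frame(chr = chr, id = sprintf("m%d", seq_len(m)),
                    bp = bp, cm = bp / 1e6, a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  if (is.null(breed)) breed <- rep("X", n)
  genotype_panel(hap, map, ids = sprintf("i%d", seq_len(n)), breed = breed)
}

# Random panel in Hardy-Weinberg equilibrium at given allele frequencies.
hwe_panel <- function(n, p, breed = NULL, spacing = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(p)
  hap <- matrix(rbinom(2 * n * m, 1, rep(p, each = 2 * n)), 2 * n, m)
  toy_panel(hap, breed = breed, spacing = spacing)
}

# Small multi-breed founder panel (shared across tests that need realistic
# LD / hierarchy without the full-scale cost).
small_founder_config <- function(seed, n_markers = 1200, n_chr = 3) {
  founder_config(n_breeds = 6, groups = rep(1:3, each = 2),
                 founders_per_breed = 12,
                 n_markers = n_markers, n_chr = n_chr,
                 ne_base = 60, gen_base = 30,
                 ne_group = 40, gen_group = 15,
                 ne_breed = 25, gen_breed = 10,
                 seed = seed)
}
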