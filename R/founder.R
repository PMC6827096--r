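#' Configuration for the synthetic founder generator
#'
#' Parameters of a forward-in-time drift/recombination simulation that
#' produces phased founder genotypes for a set of breeds with a
#' three-level hierarchy: one ancestral random-mating population, a split
#' into breed groups, then a split of each group into breeds. Defaults
#' emulate a panel of 10 small indigenous cattle breeds genotyped at
#' high density: 21-26 founders per breed, 3 groups of 4+3+3 breeds,
#' 20,000 markers at ~4 kb mean spacing.
#'
#' The recombination rate default (80 cM/Mb) is deliberately inflated
#' relative to the cattle genome average so that the scaled-down ~80 Mb
#' genome carries an effective number of independent segments comparable
#' to a full genome; it is a calibration knob, not a biological
#' estimate.
#'
#' @param n_breeds number of breeds.
#' @param groups integer vector of length `n_breeds` assigning each breed
#'   to a group (default 3 groups of 4+3+3).
#' @param founders_per_breed founders sampled per breed at the end of the
#'   simulation (default: counts between 21 and 26 typical of small
#'   indigenous breed panels).
#' @param breed_names labels for the breeds.
#' @param n_markers,n_chr total marker count and number of chromosomes
#'   (markers split evenly across chromosomes).
#' @param marker_spacing_bp mean physical spacing in bp; inter-marker gaps
#'   are drawn from an exponential distribution with this mean so that
#'   short-distance LD bins are populated.
#' @param recomb_rate_cm_mb recombination rate, cM per Mb.
#' @param ne_base,gen_base effective size and generation count of the
#'   ancestral population.
#' @param ne_group,gen_group effective size and generations after the
#'   group split.
#' @param ne_breed,gen_breed effective size and generations after the
#'   breed split.
#' @param ancestral_maf_range range of the uniform distribution for
#'   ancestral allele frequencies.
#' @param drop_monomorphic drop markers monomorphic across all founders
#'   (recommended: they carry no information and break GRM scaling).
#' @param seed integer seed for all randomness in [generate_founders()].
#'
#' @return an object of class `founder_config` (a validated list).
#' @export
founder_config <- function(n_breeds = 10L,
                           groups = rep(1:3, c(4L, 3L, 3L)),
                           founders_per_breed = c(21L, 24L, 25L, 26L, 24L,
                                                  22L, 23L, 26L, 25L, 24L),
                           breed_names = sprintf("B%02d", seq_len(n_breeds)),
                           n_markers = 20000L,
                           n_chr = 10L,
                           marker_spacing_bp = 4000,
                           recomb_rate_cm_mb = 80,
                           ne_base = 200L, gen_base = 100L,
                           ne_group = 100L, gen_group = 50L,
                           ne_breed = 50L, gen_breed = 30L,
                           ancestral_maf_range = c(0.05, 0.95),
                           drop_monomorphic = TRUE,
                           seed = NULL) {
  n_breeds <- as.integer(n_breeds)
  if (length(founders_per_breed) == 1L)
    founders_per_breed <- rep(founders_per_breed, n_breeds)
  if (length(groups) != n_breeds)
    stop("'groups' must assign every breed to a group")
  if (length(founders_per_breed) != n_breeds)
    stop("'founders_per_breed' must have one entry per breed")
  if (any(founders_per_breed < 1L))
    stop("every breed needs at least one founder")
  if (any(founders_per_breed > ne_breed))
    stop("founders_per_breed cannot exceed ne_breed")
  if (n_markers < 1L || n_chr < 1L || n_markers < n_chr)
    stop("need at least one marker per chromosome")
  if (marker_spacing_bp <= 0 || recomb_rate_cm_mb < 0)
    stop("spacing must be positive and recombination rate non-negative")
  cfg <- list(n_breeds = n_breeds, groups = as.integer(groups),
              founders_per_breed = as.integer(founders_per_breed),
              breed_names = breed_names,
              n_markers = as.integer(n_markers), n_chr = as.integer(n_chr),
              marker_spacing_bp = marker_spacing_bp,
              recomb_rate_cm_mb = recomb_rate_cm_mb,
              ne_base = as.integer(ne_base), gen_base = as.integer(gen_base),
              ne_group = as.integer(ne_group), gen_group = as.integer(gen_group),
              ne_breed = as.integer(ne_breed), gen_breed = as.integer(gen_breed),
              ancestral_maf_range = ancestral_maf_range,
              drop_monomorphic = isTRUE(drop_monomorphic), seed = seed)
  class(cfg) <- "founder_config"
  cfg
}

#' Generate phased multi-breed founder genotypes
#'
#' Forward-in-time simulation: an ancestral random-mating population with
#' per-generation Poisson recombination drifts for `gen_base` generations;
#' it then splits into groups (each founded by a bottleneck draw from the
#' ancestral pool) which drift for `gen_group` generations, and each group
#' splits into its breeds which drift for `gen_breed` generations.
#' Founders are sampled from the final generation of each breed.
#'
#' @param config a [founder_config()].
#' @return a phased [genotype_panel()] of `sum(founders_per_breed)`
#'   individuals. The config (including seed) is attached as attribute
#'   `"config"`.
#' @export
generate_founders <- function(config = founder_config()) {
  stopifnot(inherits(config, "founder_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  map <- simulate_marker_map(config)
  chrs <- chromosome_layout(map)
  m <- nrow(map)

  # ancestral population; haplotypes are columns during evolution
  p0 <- stats::runif(m, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  H <- matrix(stats::rbinom(2L * config$ne_base * m, 1L, p0),
              m, 2L * config$ne_base)
  H <- evolve(H, config$ne_base, config$gen_base, chrs)

  group_ids <- sort(unique(config$groups))
  group_pools <- lapply(group_ids, function(g) {
    Hg <- bottleneck(H, config$ne_group)
    evolve(Hg, config$ne_group, config$gen_group, chrs)
  })

  panels <- vector("list", config$n_breeds)
  for (b in seq_len(config$n_breeds)) {
    Hb <- bottleneck(group_pools[[match(config$groups[b], group_ids)]],
                     config$ne_breed)
    Hb <- evolve(Hb, config$ne_breed, config$gen_breed, chrs)
    keep <- sort(sample.int(config$ne_breed, config$founders_per_breed[b]))
    panels[[b]] <- t(Hb[, hap_rows(keep), drop = FALSE])
  }

  hap <- do.call(rbind, panels)
  breed <- rep(config$breed_names, config$founders_per_breed)
  ids <- unlist(lapply(seq_len(config$n_breeds), function(b)
    sprintf("%s_F%02d", config$breed_names[b],
            seq_len(config$founders_per_breed[b]))), use.names = FALSE)
  panel <- genotype_panel(hap, map, ids, breed)

  if (config$drop_monomorphic) {
    p <- allele_freq(panel)
    poly <- which(p > 0 & p < 1)
    if (length(poly) == 0L) stop("all markers monomorphic across founders")
    panel <- subset_panel(panel, markers = poly)
  }
  attr(panel, "config") <- config
  panel
}

simulate_marker_map <- function(config) {
  per_chr <- rep(config$n_markers %/% config$n_chr, config$n_chr)
  rem <- config$n_markers %% config$n_chr
  if (rem > 0L) per_chr[seq_len(rem)] <- per_chr[seq_len(rem)] + 1L
  maps <- lapply(seq_len(config$n_chr), function(ch) {
    gaps <- pmax(1, round(stats::rexp(per_chr[ch], 1 / config$marker_spacing_bp)))
    bp <- cumsum(gaps)
    data.frame(chr = ch,
               id = sprintf("snp%d_%d", ch, seq_len(per_chr[ch])),
               bp = bp,
               cm = bp / 1e6 * config$recomb_rate_cm_mb,
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

chromosome_layout <- function(map) {
  idx_by_chr <- split(seq_len(nrow(map)), map$chr)
  cm_m <- numeric(nrow(map))
  len_m <- numeric(length(idx_by_chr))
  start <- end <- integer(length(idx_by_chr))
  for (i in seq_along(idx_by_chr)) {
    idx <- idx_by_chr[[i]]
    cm <- map$cm[idx]
    cm_m[idx] <- (cm - cm[1]) / 100
    len_m[i] <- (cm[length(cm)] - cm[1]) / 100
    start[i] <- idx[1] - 1L
    end[i] <- idx[length(idx)] - 1L
  }
  list(start0 = start, end0 = end, cm_m = cm_m, len_m = len_m)
}

# H is markers x haplotypes during evolution
bottleneck <- function(H, ne_new) {
  N <- ncol(H) %/% 2L
  H[, hap_rows(sample.int(N, ne_new, replace = TRUE)), drop = FALSE]
}

evolve <- function(H, ne, generations, chrs) {
  if (generations < 1L) return(H)
  for (g in seq_len(generations)) H <- next_generation(H, ne, chrs)
  H
}

# One generation of random mating with per-chromosome Poisson crossovers
# at uniform genetic positions; compiled inner loop.
next_generation <- function(H, n_off, chrs) {
  cpp_next_generation(H, as.integer(n_off), chrs$start0, chrs$end0,
                      chrs$cm_m, chrs$len_m)
}
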