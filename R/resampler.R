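#' Configuration for block-resampling genotype expansion
#'
#' @param block_size_markers number of adjacent markers per resampling
#'   block (blocks never span chromosomes; the last block on a chromosome
#'   may be shorter).
#' @param n_per_breed number of simulated individuals per breed.
#' @param seed integer seed.
#' @return an object of class `resample_config`.
#' @export
resample_config <- function(block_size_markers = 500L, n_per_breed = 1500L,
                            seed = NULL) {
  block_size_markers <- as.integer(block_size_markers)
  n_per_breed <- as.integer(n_per_breed)
  if (block_size_markers < 1L) stop("block size must be >= 1 marker")
  if (n_per_breed < 1L) stop("must simulate at least one individual")
  structure(list(block_size_markers = block_size_markers,
                 n_per_breed = n_per_breed, seed = seed),
            class = "resample_config")
}

#' Marker-block partition of a map
#'
#' Consecutive blocks of `block_size` markers from the start of each
#' chromosome; deterministic given the map.
#'
#' @param map a marker map (see [genotype_panel()]).
#' @param block_size markers per block.
#' @return list of integer marker-index vectors, one per block.
#' @export
marker_blocks <- function(map, block_size) {
  out <- list()
  for (idx in split(seq_len(nrow(map)), map$chr)) {
    starts <- seq(1L, length(idx), by = block_size)
    for (s in starts)
      out[[length(out) + 1L]] <- idx[s:min(s + block_size - 1L, length(idx))]
  }
  out
}

#' Expand one breed by haplotype-block resampling
#'
#' Simulates individuals as mosaics of founder haplotype segments: the
#' markers are partitioned into consecutive blocks of
#' `block_size_markers` within each chromosome, and for every simulated
#' gamete and block independently one founder haplotype segment is drawn
#' uniformly with replacement from the breed's `2 * n_founders` haplotype
#' pool. Within a block, LD and allele frequencies of the founders are
#' preserved; across block boundaries, segments are independent.
#'
#' Founders must be phased and complete; isolated missing founder calls
#' are imputed to the per-marker major allele with a warning.
#'
#' @param panel founder [genotype_panel()].
#' @param breed breed label to expand (must be present in `panel`).
#' @param config a [resample_config()].
#' @return a phased `genotype_panel` of `n_per_breed` simulated
#'   individuals with the founders' marker map and the breed label.
#'   Block boundaries are attached as attribute `"blocks"`.
#' @export
expand_breed <- function(panel, breed, config = resample_config()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "resample_config"))
  if (!breed %in% panel$breed) stop("breed '", breed, "' not present in panel")
  if (!is.null(config$seed)) set.seed(config$seed)
  idx <- which(panel$breed == breed)
  Hf <- panel$haplotypes[hap_rows(idx), , drop = FALSE]
  if (any(Hf == as.raw(255))) {
    warning("missing founder calls imputed to the per-marker major allele")
    Hi <- matrix(as.integer(Hf), nrow(Hf), ncol(Hf))
    miss <- Hi == 255L
    Hi[miss] <- 0L
    p <- colSums(Hi) / (nrow(Hi) - colSums(miss))
    major <- as.integer(p >= 0.5)
    Hi[miss] <- major[col(Hi)[miss]]
    Hf <- matrix(as.raw(Hi), nrow(Hi), ncol(Hi))
  }
  blocks <- marker_blocks(panel$map, config$block_size_markers)
  n_hap <- nrow(Hf)
  n_gam <- 2L * config$n_per_breed
  out <- matrix(as.raw(0), n_gam, ncol(Hf))
  for (bk in blocks) {
    draw <- sample.int(n_hap, n_gam, replace = TRUE)
    out[, bk] <- Hf[draw, bk, drop = FALSE]
  }
  sim <- genotype_panel(out, panel$map,
                        sprintf("%s_S%04d", breed, seq_len(config$n_per_breed)),
                        rep(breed, config$n_per_breed))
  attr(sim, "blocks") <- blocks
  sim
}

#' Expand every breed of a founder panel
#'
#' Applies [expand_breed()] to each breed in turn under a single seed.
#'
#' @inheritParams expand_breed
#' @return a `genotype_panel` stacking all simulated breeds.
#' @export
expand_panel <- function(panel, config = resample_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  sub <- config
  sub$seed <- NULL
  breeds <- unique(panel$breed)
  sim <- bind_panels(lapply(breeds, function(b) expand_breed(panel, b, sub)))
  attr(sim, "blocks") <- marker_blocks(panel$map, config$block_size_markers)
  sim
}
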