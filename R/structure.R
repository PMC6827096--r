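#' Principal components of a genotype panel
#'
#' PCA of the column-centered dosage matrix (individuals x markers) via
#' [stats::prcomp()]; components are ordered by decreasing explained
#' variance.
#'
#' @param panel a [genotype_panel()].
#' @param n_components number of components to retain.
#' @param individuals optional subset of individuals.
#' @return an object of class `panel_pca`: list with `scores`
#'   (individuals x components, rownames = ids), `sdev` (all component
#'   standard deviations), and `breed`.
#' @export
panel_pca <- function(panel, n_components = 10L, individuals = NULL) {
  idx <- resolve_ind(panel, individuals)
  if (length(idx) < 2L) stop("PCA needs at least 2 individuals")
  X <- dosage(panel, individuals = idx)
  storage.mode(X) <- "double"
  keep <- which(matrixStats_colVars(X) > 0)
  if (length(keep) < 2L) stop("fewer than 2 polymorphic markers; PCA undefined")
  pr <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                      rank. = min(n_components, length(idx) - 1L))
  structure(list(scores = pr$x, sdev = pr$sdev, breed = panel$breed[idx]),
            class = "panel_pca")
}

# column variances without extra dependencies
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - colSums(X)^2 / n) / (n - 1)
}

#' @export
print.panel_pca <- function(x, ...) {
  ve <- x$sdev^2 / sum(x$sdev^2)
  cat("panel_pca:", nrow(x$scores), "individuals,", ncol(x$scores),
      "components;", sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
                             100 * ve[1], 100 * ve[2]))
  invisible(x)
}

#' K-means grouping of breeds in PC space
#'
#' Clusters breed centroids (not individuals) in the top principal
#' components, so that the breed-level group assignment is well defined.
#' Uses [stats::kmeans()] with many restarts; deterministic under the
#' seed.
#'
#' @param pca a [panel_pca()] object, or a score matrix.
#' @param breed_labels breed label per row of the score matrix (taken
#'   from the `panel_pca` object when available).
#' @param k number of groups.
#' @param n_pcs number of leading components used (default 5).
#' @param nstart random restarts.
#' @param seed seed for the restarts.
#' @return named integer vector mapping each breed to a group id in
#'   `1..k`.
#' @export
kmeans_groups <- function(pca, breed_labels = NULL, k = 3L, n_pcs = 5L,
                          nstart = 50L, seed = 1L) {
  if (inherits(pca, "panel_pca")) {
    scores <- pca$scores
    if (is.null(breed_labels)) breed_labels <- pca$breed
  } else scores <- as.matrix(pca)
  if (is.null(breed_labels)) stop("breed labels required")
  breeds <- unique(breed_labels)
  if (k > length(breeds)) stop("k exceeds the number of breeds")
  use <- seq_len(min(n_pcs, ncol(scores)))
  cent <- rowsum(scores[, use, drop = FALSE], breed_labels) /
    as.vector(table(breed_labels)[sort(breeds)])
  cent <- cent[breeds, , drop = FALSE]
  if (k == length(breeds)) {
    # one breed per group; no clustering needed
    out <- seq_len(k)
  } else {
    set.seed(seed)
    km <- stats::kmeans(cent, centers = k, nstart = nstart)
    out <- km$cluster
  }
  names(out) <- breeds
  out
}

#' Distance bins for persistence-of-phase analysis
#'
#' Default binning: 2.5 kb steps over 0-10 kb, 10 kb steps over
#' 10-100 kb, 100 kb steps over 100-1000 kb.
#'
#' @param small,medium,large numeric length-2 vectors `c(limit, step)` in
#'   bp for the three distance regimes.
#' @return data frame with columns `lower`, `upper` (bp, bins are
#'   `(lower, upper]`).
#' @export
phase_bins <- function(small = c(10e3, 2.5e3), medium = c(100e3, 10e3),
                       large = c(1000e3, 100e3)) {
  edges <- unique(c(seq(0, small[1], by = small[2]),
                    seq(small[1], medium[1], by = medium[2]),
                    seq(medium[1], large[1], by = large[2])))
  if (any(diff(edges) <= 0)) stop("bin edges must be increasing")
  data.frame(lower = edges[-length(edges)], upper = edges[-1])
}

# All same-chromosome marker pairs with physical distance <= max_dist.
ld_pairs <- function(map, max_dist) {
  is <- js <- list()
  for (idx in split(seq_len(nrow(map)), map$chr)) {
    bp <- map$bp[idx]
    jmax <- findInterval(bp + max_dist, bp)
    cnt <- pmax(jmax - seq_along(idx), 0L)
    ii <- rep(seq_along(idx), cnt)
    is[[length(is) + 1L]] <- idx[ii]
    js[[length(js) + 1L]] <- idx[ii + sequence(cnt)]
  }
  i <- unlist(is, use.names = FALSE)
  j <- unlist(js, use.names = FALSE)
  data.frame(i = i, j = j, dist = map$bp[j] - map$bp[i])
}

# Signed LD correlation r for the given marker pairs, from haplotype
# (default) or dosage columns. Chunked crossprod keeps memory bounded.
# Returns NA for pairs involving a monomorphic/constant marker.
pair_r <- function(panel, pairs, statistic = c("haplotype", "dosage")) {
  statistic <- match.arg(statistic)
  getX <- function(markers) {
    M <- if (statistic == "haplotype") haplotypes(panel, markers = markers)
         else dosage(panel, markers = markers)
    storage.mode(M) <- "double"
    M
  }
  m <- n_markers(panel)
  # global means and sds (population denominator: consistent with E[xy] below)
  mu <- sg <- numeric(m)
  step <- 4096L
  for (s in seq(1L, m, by = step)) {
    cols <- s:min(s + step - 1L, m)
    Xc <- getX(cols)
    mu[cols] <- colMeans(Xc)
    sg[cols] <- sqrt(colMeans(Xc^2) - mu[cols]^2)
  }
  r <- rep(NA_real_, nrow(pairs))
  ord <- order(pairs$i)
  pi_ <- pairs$i[ord]; pj_ <- pairs$j[ord]
  chunk <- 1024L
  pos <- 1L
  n_p <- length(pi_)
  while (pos <= n_p) {
    a <- pi_[pos]
    end <- pos
    last <- min(pos + 200000L, n_p)
    end <- max(which(pi_[pos:last] < a + chunk)) + pos - 1L
    sel <- pos:end
    cols <- a:max(pj_[sel])
    Xc <- getX(cols)
    C <- crossprod(Xc) / nrow(Xc)
    il <- pi_[sel] - a + 1L
    jl <- pj_[sel] - a + 1L
    r[sel] <- (C[cbind(il, jl)] - mu[pi_[sel]] * mu[pj_[sel]]) /
      (sg[pi_[sel]] * sg[pj_[sel]])
    pos <- end + 1L
  }
  out <- numeric(nrow(pairs))
  out[ord] <- r
  out[!is.finite(out)] <- NA_real_
  out
}

#' Persistence of LD phase between two panels
#'
#' For every same-chromosome marker pair whose distance falls within the
#' binning, computes the signed LD correlation `r` in each panel (from
#' haplotype frequencies by default) and reports, per distance bin, the
#' Pearson correlation of the paired `r` values across the bin's marker
#' pairs. Pairs monomorphic in either panel are skipped; bins without
#' eligible pairs are reported as `NA`, never zero.
#'
#' @param panel_a,panel_b phased [genotype_panel()]s over an identical
#'   marker map.
#' @param bins a [phase_bins()] data frame.
#' @param statistic `"haplotype"` (signed r from phased haplotypes) or
#'   `"dosage"` (composite r from unphased dosages).
#' @return data frame with columns `lower`, `upper`, `n_pairs`,
#'   `correlation`.
#' @export
phase_persistence <- function(panel_a, panel_b, bins = phase_bins(),
                              statistic = c("haplotype", "dosage")) {
  statistic <- match.arg(statistic)
  if (!identical(panel_a$map$bp, panel_b$map$bp) ||
      !identical(panel_a$map$chr, panel_b$map$chr))
    stop("panels must share an identical marker map")
  pairs <- ld_pairs(panel_a$map, max(bins$upper))
  pairs <- pairs[pairs$dist > min(bins$lower), , drop = FALSE]
  ra <- pair_r(panel_a, pairs, statistic)
  rb <- pair_r(panel_b, pairs, statistic)
  bin <- findInterval(pairs$dist, bins$lower, left.open = TRUE)
  bin[pairs$dist > max(bins$upper)] <- NA_integer_
  n_pairs <- correlation <- numeric(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    sel <- which(bin == b & is.finite(ra) & is.finite(rb))
    n_pairs[b] <- length(sel)
    correlation[b] <- if (length(sel) >= 3L &&
                          stats::sd(ra[sel]) > 0 && stats::sd(rb[sel]) > 0)
      stats::cor(ra[sel], rb[sel]) else NA_real_
  }
  cbind(bins, n_pairs = n_pairs, correlation = correlation)
}

#' Mean r-squared LD decay by distance bin
#'
#' @param panel a phased [genotype_panel()].
#' @param breaks increasing distance break points in bp; bins are
#'   `(breaks[k], breaks[k+1]]`.
#' @param statistic see [phase_persistence()].
#' @return data frame with `lower`, `upper`, `n_pairs`, `mean_r2`.
#' @export
ld_decay <- function(panel, breaks = c(0, 1e4, 1e5, 1e6),
                     statistic = c("haplotype", "dosage")) {
  statistic <- match.arg(statistic)
  pairs <- ld_pairs(panel$map, max(breaks))
  pairs <- pairs[pairs$dist > min(breaks), , drop = FALSE]
  r <- pair_r(panel, pairs, statistic)
  bin <- findInterval(pairs$dist, breaks, left.open = TRUE)
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1])
  out$n_pairs <- as.integer(tabulate(bin[is.finite(r)], nrow(out)))
  out$mean_r2 <- vapply(seq_len(nrow(out)), function(b) {
    sel <- which(bin == b & is.finite(r))
    if (length(sel)) mean(r[sel]^2) else NA_real_
  }, numeric(1))
  out
}

#' Pairwise FST between breeds
#'
#' Hudson's estimator averaged over markers (ratio of sums), computed
#' from haplotype allele counts.
#'
#' @param panel a [genotype_panel()] with at least two breeds.
#' @return symmetric matrix of FST values, breeds in rows/columns.
#' @export
pairwise_fst <- function(panel) {
  breeds <- unique(panel$breed)
  if (length(breeds) < 2L) stop("need at least two breeds")
  freqs <- sapply(breeds, function(b)
    allele_freq(panel, individuals = which(panel$breed == b)))
  nh <- sapply(breeds, function(b) 2 * sum(panel$breed == b))
  out <- matrix(0, length(breeds), length(breeds),
                dimnames = list(breeds, breeds))
  for (a in seq_along(breeds)) for (b in seq_along(breeds)) {
    if (b <= a) next
    p1 <- freqs[, a]; p2 <- freqs[, b]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (nh[a] - 1) - p2 * (1 - p2) / (nh[b] - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    keep <- den > 0
    out[a, b] <- out[b, a] <- sum(num[keep]) / sum(den[keep])
  }
  out
}
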