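#' Phased multi-breed genotype panel
#'
#' A `genotype_panel` holds phased diploid genotypes for a set of
#' individuals: a marker map, two haplotypes per individual stored as a
#' compact allele matrix, individual identifiers and a breed label per
#' individual. Alleles are coded 0/1 (the map records the symbolic allele
#' for each code); missing calls are allowed and propagate to dosages as
#' `NA`.
#'
#' @param haplotypes integer (or raw) matrix with `2 * n` rows and `m`
#'   columns; rows `2i - 1` and `2i` are the two haplotypes of individual
#'   `i`. Entries must be 0, 1 or `NA` (missing).
#' @param map data frame with columns `chr` (integer chromosome id),
#'   `id` (marker name), `bp` (physical position, base pairs), `cm`
#'   (genetic position, centiMorgans), `a1`, `a2` (symbolic alleles for
#'   codes 0 and 1). Positions must be strictly increasing within each
#'   chromosome and `cm` non-decreasing with `bp`.
#' @param ids character vector of `n` unique individual ids.
#' @param breed character vector of `n` breed labels.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(haplotypes, map, ids, breed) {
  if (is.integer(haplotypes) || is.double(haplotypes)) {
    h <- haplotypes
    h[is.na(h)] <- 255
    storage.mode(h) <- "integer"
    raw_h <- matrix(as.raw(h), nrow(h), ncol(h))
  } else if (is.raw(haplotypes)) {
    raw_h <- haplotypes
  } else {
    stop("'haplotypes' must be an integer or raw matrix")
  }
  n2 <- nrow(raw_h)
  if (n2 %% 2L != 0L) stop("haplotype matrix must have an even number of rows")
  n <- n2 %/% 2L
  if (length(ids) != n) stop("length(ids) must equal the number of individuals")
  if (length(breed) != n) stop("length(breed) must equal the number of individuals")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  validate_marker_map(map)
  if (nrow(map) != ncol(raw_h)) stop("map rows must match haplotype columns")
  structure(
    list(haplotypes = raw_h, map = map, ids = as.character(ids),
         breed = as.character(breed)),
    class = "genotype_panel"
  )
}

validate_marker_map <- function(map) {
  req <- c("chr", "id", "bp", "cm", "a1", "a2")
  if (!is.data.frame(map) || !all(req %in% names(map)))
    stop("map must be a data frame with columns ", paste(req, collapse = ", "))
  for (ch in unique(map$chr)) {
    bp <- map$bp[map$chr == ch]
    cm <- map$cm[map$chr == ch]
    if (any(diff(bp) <= 0))
      stop("physical positions must be strictly increasing within chromosome ", ch)
    if (any(diff(cm) < 0))
      stop("genetic positions must be non-decreasing within chromosome ", ch)
  }
  invisible(map)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", n_ind(x), "individuals,", n_markers(x), "markers,",
      length(unique(x$breed)), "breed(s),",
      length(unique(x$map$chr)), "chromosome(s)\n")
  tb <- table(x$breed)
  cat("breeds:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals / markers in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_ind <- function(panel) length(panel$ids)

#' @rdname n_ind
#' @export
n_markers <- function(panel) nrow(panel$map)

hap_rows <- function(ind_idx) {
  # haplotype row indices for individual indices
  as.vector(rbind(2L * ind_idx - 1L, 2L * ind_idx))
}

#' Extract haplotypes as a 0/1 integer matrix
#'
#' @param panel a `genotype_panel`.
#' @param individuals optional individual index or id vector.
#' @param markers optional marker index vector.
#' @return integer matrix (`2 * n` rows) with `NA` for missing alleles.
#' @export
haplotypes <- function(panel, individuals = NULL, markers = NULL) {
  idx <- resolve_ind(panel, individuals)
  h <- panel$haplotypes[hap_rows(idx), if (is.null(markers)) TRUE else markers,
                        drop = FALSE]
  out <- matrix(as.integer(h), nrow(h), ncol(h))
  out[out == 255L] <- NA_integer_
  out
}

resolve_ind <- function(panel, individuals) {
  if (is.null(individuals)) return(seq_along(panel$ids))
  if (is.character(individuals)) {
    idx <- match(individuals, panel$ids)
    if (anyNA(idx)) stop("unknown individual id(s)")
    idx
  } else as.integer(individuals)
}

#' Genotype dosage matrix
#'
#' Allele dosage (0/1/2 copies of the code-1 allele) per individual and
#' marker; `NA` where either haplotype call is missing.
#'
#' @inheritParams haplotypes
#' @return integer matrix, individuals in rows (named by id), markers in
#'   columns (named by marker id).
#' @export
dosage <- function(panel, individuals = NULL, markers = NULL) {
  idx <- resolve_ind(panel, individuals)
  jdx <- if (is.null(markers)) seq_len(n_markers(panel)) else markers
  h1 <- panel$haplotypes[2L * idx - 1L, jdx, drop = FALSE]
  h2 <- panel$haplotypes[2L * idx, jdx, drop = FALSE]
  d1 <- matrix(as.integer(h1), nrow(h1), ncol(h1))
  d2 <- matrix(as.integer(h2), nrow(h2), ncol(h2))
  d1[d1 == 255L] <- NA_integer_
  d2[d2 == 255L] <- NA_integer_
  out <- d1 + d2
  dimnames(out) <- list(panel$ids[idx], panel$map$id[jdx])
  out
}

#' Subset a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param individuals individual indices or ids (default all).
#' @param markers marker indices (default all).
#' @return a `genotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, individuals = NULL, markers = NULL) {
  idx <- resolve_ind(panel, individuals)
  jdx <- if (is.null(markers)) seq_len(n_markers(panel)) else markers
  genotype_panel(panel$haplotypes[hap_rows(idx), jdx, drop = FALSE],
                 droplevels(panel$map[jdx, , drop = FALSE]),
                 panel$ids[idx], panel$breed[idx])
}

#' Per-marker allele frequency
#'
#' Frequency of the code-1 allele, computed from non-missing haplotypes.
#'
#' @param panel a `genotype_panel`.
#' @param individuals optional subset of individuals.
#' @return numeric vector of length `n_markers(panel)`.
#' @export
allele_freq <- function(panel, individuals = NULL) {
  idx <- resolve_ind(panel, individuals)
  rows <- hap_rows(idx)
  m_tot <- n_markers(panel)
  out <- numeric(m_tot)
  step <- max(1L, 2^24 %/% max(length(rows), 1L))  # bound temporaries
  for (s in seq(1L, m_tot, by = step)) {
    jdx <- s:min(s + step - 1L, m_tot)
    h <- panel$haplotypes[rows, jdx, drop = FALSE]
    m <- matrix(as.integer(h), nrow(h), ncol(h))
    miss <- m == 255L
    m[miss] <- 0L
    out[jdx] <- colSums(m) / (nrow(m) - colSums(miss))
  }
  out
}

#' Combine panels sharing a marker map
#'
#' @param ... `genotype_panel` objects with identical marker maps.
#' @return a single `genotype_panel` stacking all individuals.
#' @export
bind_panels <- function(...) {
  panels <- list(...)
  if (length(panels) == 1L && is.list(panels[[1]]) &&
      !inherits(panels[[1]], "genotype_panel"))
    panels <- panels[[1]]
  map <- panels[[1]]$map
  for (p in panels[-1])
    if (!identical(p$map$id, map$id) || !identical(p$map$bp, map$bp))
      stop("panels must share an identical marker map")
  genotype_panel(do.call(rbind, lapply(panels, `[[`, "haplotypes")), map,
                 unlist(lapply(panels, `[[`, "ids"), use.names = FALSE),
                 unlist(lapply(panels, `[[`, "breed"), use.names = FALSE))
}
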