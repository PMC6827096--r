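#' Write a panel as PLINK text files (.ped/.map)
#'
#' The breed label is stored in the family-id column; phase is preserved
#' (the two alleles of a marker are written haplotype-1 first). Missing
#' calls are written as `0 0`.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  map <- panel$map
  utils::write.table(
    data.frame(map$chr, map$id, format(map$cm, trim = TRUE), map$bp),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  n <- n_ind(panel)
  m <- n_markers(panel)
  h1 <- matrix(as.integer(panel$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE]), n, m)
  h2 <- matrix(as.integer(panel$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE]), n, m)
  code <- function(h, j) {
    out <- character(length(h))
    out[h == 0L] <- panel$map$a1[j]
    out[h == 1L] <- panel$map$a2[j]
    out[h == 255L] <- "0"
    out
  }
  miss <- h1 == 255L | h2 == 255L
  geno <- matrix("", n, 2L * m)
  for (j in seq_len(m)) {
    a1 <- code(h1[, j], j)
    a2 <- code(h2[, j], j)
    a1[miss[, j]] <- "0"; a2[miss[, j]] <- "0"
    geno[, 2L * j - 1L] <- a1
    geno[, 2L * j] <- a2
  }
  ped <- cbind(panel$breed, panel$ids, "0", "0", "0", "-9", geno)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}

#' Read PLINK text files (.ped/.map) into a panel
#'
#' Breed labels are taken from the family-id column. Allele codes are
#' assigned alphabetically per marker: the lexicographically smaller
#' observed allele becomes code 0. For markers where only one allele is
#' observed, that allele is code 0.
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return a [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path))
    stop("missing ", map_path, " or ", ped_path)
  mp <- utils::read.table(map_path, header = FALSE, sep = "\t",
                          col.names = c("chr", "id", "cm", "bp"),
                          stringsAsFactors = FALSE)
  m <- nrow(mp)
  ped <- utils::read.table(ped_path, header = FALSE, sep = "",
                           colClasses = "character")
  if (ncol(ped) != 6L + 2L * m)
    stop("inconsistent marker counts between .map (", m, ") and .ped (",
         (ncol(ped) - 6L) / 2, ")")
  n <- nrow(ped)
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a_first <- al[, seq(1L, 2L * m, 2L), drop = FALSE]
  a_second <- al[, seq(2L, 2L * m, 2L), drop = FALSE]

  a1 <- a2 <- character(m)
  h1 <- matrix(255L, n, m)
  h2 <- matrix(255L, n, m)
  for (j in seq_len(m)) {
    obs <- unique(c(a_first[, j], a_second[, j]))
    obs <- sort(obs[obs != "0"])
    if (length(obs) > 2L)
      stop("marker ", mp$id[j], " has more than two allele codes: ",
           paste(obs, collapse = "/"))
    a1[j] <- if (length(obs) >= 1L) obs[1] else "A"
    a2[j] <- if (length(obs) == 2L) obs[2] else "B"
    h1[, j] <- ifelse(a_first[, j] == "0", 255L,
                      ifelse(a_first[, j] == a1[j], 0L, 1L))
    h2[, j] <- ifelse(a_second[, j] == "0", 255L,
                      ifelse(a_second[, j] == a1[j], 0L, 1L))
  }
  # either allele missing marks the genotype missing (ped has no half-calls)
  miss <- h1 == 255L | h2 == 255L
  h1[miss] <- 255L; h2[miss] <- 255L

  hap <- matrix(255L, 2L * n, m)
  hap[seq(1L, 2L * n, 2L), ] <- h1
  hap[seq(2L, 2L * n, 2L), ] <- h2
  map <- data.frame(chr = mp$chr, id = mp$id, bp = as.numeric(mp$bp),
                    cm = as.numeric(mp$cm), a1 = a1, a2 = a2,
                    stringsAsFactors = FALSE)
  genotype_panel(hap, map, ids = ped[[2]], breed = ped[[1]])
}
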