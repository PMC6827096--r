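#' Genotype quality-control thresholds
#'
#' Standard panel QC: samples by call rate, then SNPs by call rate, minor
#' allele frequency and Hardy-Weinberg equilibrium, optionally restricted
#' to autosomes.
#'
#' @param sample_call_rate_min minimum per-sample call rate.
#' @param snp_call_rate_min minimum per-SNP call rate.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum HWE p-value (SNPs below are removed).
#' @param autosomes_only drop markers on non-numeric chromosome codes
#'   (e.g. "X", "Y", "MT").
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.90,
                          snp_call_rate_min = 0.90,
                          maf_min = 0.01,
                          hwe_p_min = 1e-6,
                          autosomes_only = TRUE) {
  vals <- c(sample_call_rate_min, snp_call_rate_min, maf_min, hwe_p_min)
  if (any(vals < 0 | vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 snp_call_rate_min = snp_call_rate_min,
                 maf_min = maf_min, hwe_p_min = hwe_p_min,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against HWE expectations at the observed allele frequency
#' (default), or the mid-p exact test. Monomorphic SNPs return `p = 1`
#' by convention.
#'
#' @param counts genotype-count triple `c(n0, n1, n2)` for dosages
#'   0 / 1 / 2.
#' @param method `"chisq"` (asymptotic) or `"exact"` (mid-p exact test on
#'   heterozygote counts).
#' @return p-value.
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (length(counts) != 3L || any(counts < 0)) stop("counts must be 3 non-negative values")
  n <- sum(counts)
  if (n == 0) stop("empty genotype counts")
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  if (method == "chisq") {
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    x2 <- sum((counts - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # mid-p exact: distribution of heterozygote count given minor-allele count
  n_minor <- as.integer(round(2 * n * min(p, 1 - p)))
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_min + 1) - lgamma(hom_maj + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(counts[2], hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele count")
  min(1, sum(pr[pr <= pr[obs]]) - 0.5 * pr[obs])
}

# vectorized 1-df chi-square HWE p-values from a dosage matrix
hwe_pvalues <- function(X) {
  n0 <- colSums(X == 0L, na.rm = TRUE)
  n1 <- colSums(X == 1L, na.rm = TRUE)
  n2 <- colSums(X == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), 0)
  out <- rep(1, ncol(X))
  ok <- p > 0 & p < 1
  e0 <- n * (1 - p)^2; e1 <- 2 * n * p * (1 - p); e2 <- n * p^2
  x2 <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  out[ok] <- stats::pchisq(x2[ok], df = 1, lower.tail = FALSE)
  out
}

#' Filter a genotype panel by quality control
#'
#' Applies, in order: autosome restriction, sample call rate, SNP call
#' rate, minor allele frequency, Hardy-Weinberg equilibrium. The order
#' (samples before SNPs, call rate before MAF before HWE) follows the
#' usual PLINK convention and is recorded in the report.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @param scope `"pooled"` (MAF/HWE on the whole panel) or `"per_breed"`
#'   (a SNP is removed if it fails MAF or HWE within any breed).
#' @param hwe_method passed to the HWE computation (`"chisq"` or
#'   `"exact"`; the vectorized chi-square is used unless `"exact"`).
#' @return list with `panel` (the filtered panel) and `report` (class
#'   `qc_report`: counts removed per rule, order of application,
#'   thresholds).
#' @export
qc_filter <- function(panel, thresholds = qc_thresholds(),
                      scope = c("pooled", "per_breed"),
                      hwe_method = c("chisq", "exact")) {
  scope <- match.arg(scope)
  hwe_method <- match.arg(hwe_method)
  stopifnot(inherits(panel, "genotype_panel"))
  if (n_ind(panel) == 0L || n_markers(panel) == 0L) stop("empty panel")
  report <- list(order = c("autosomes", "sample_call_rate", "snp_call_rate",
                           "maf", "hwe"),
                 thresholds = thresholds, scope = scope,
                 n_samples_in = n_ind(panel), n_snps_in = n_markers(panel))

  # autosomes: numeric chromosome codes only
  if (thresholds$autosomes_only) {
    chr_num <- suppressWarnings(as.numeric(as.character(panel$map$chr)))
    keep <- which(!is.na(chr_num))
    report$snps_removed_nonautosomal <- n_markers(panel) - length(keep)
    if (!length(keep)) stop("QC removed all SNPs (autosome filter)")
    if (length(keep) < n_markers(panel))
      panel <- subset_panel(panel, markers = keep)
  } else report$snps_removed_nonautosomal <- 0L

  X <- dosage(panel)
  # samples first
  cr_sample <- rowMeans(!is.na(X))
  keep_s <- which(cr_sample >= thresholds$sample_call_rate_min)
  report$samples_removed_call_rate <- n_ind(panel) - length(keep_s)
  if (!length(keep_s)) stop("QC removed all samples")
  if (length(keep_s) < n_ind(panel)) {
    panel <- subset_panel(panel, individuals = keep_s)
    X <- X[keep_s, , drop = FALSE]
  }

  # SNP call rate
  cr_snp <- colMeans(!is.na(X))
  fail_cr <- cr_snp < thresholds$snp_call_rate_min
  report$snps_removed_call_rate <- sum(fail_cr)

  per_breed_stat <- function(stat_fail) {
    # stat_fail(Xb) -> logical per marker
    fails <- lapply(unique(panel$breed), function(b)
      stat_fail(X[panel$breed == b, , drop = FALSE]))
    Reduce(`|`, fails)
  }
  maf_fail_fun <- function(Xb) {
    p <- colMeans(Xb, na.rm = TRUE) / 2
    pmin(p, 1 - p) < thresholds$maf_min
  }
  hwe_fail_fun <- function(Xb) {
    pv <- if (hwe_method == "chisq") hwe_pvalues(Xb)
          else apply(Xb, 2, function(x)
            hwe_test(c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                       sum(x == 2, na.rm = TRUE)), method = "exact"))
    pv < thresholds$hwe_p_min
  }
  fail_maf <- if (scope == "pooled") maf_fail_fun(X) else per_breed_stat(maf_fail_fun)
  fail_maf <- fail_maf & !fail_cr
  report$snps_removed_maf <- sum(fail_maf)
  fail_hwe <- if (scope == "pooled") hwe_fail_fun(X) else per_breed_stat(hwe_fail_fun)
  fail_hwe <- fail_hwe & !fail_cr & !fail_maf
  report$snps_removed_hwe <- sum(fail_hwe)

  keep_m <- which(!(fail_cr | fail_maf | fail_hwe))
  if (!length(keep_m)) stop("QC removed all SNPs")
  if (length(keep_m) < n_markers(panel))
    panel <- subset_panel(panel, markers = keep_m)
  report$n_samples_out <- n_ind(panel)
  report$n_snps_out <- n_markers(panel)
  class(report) <- "qc_report"
  list(panel = panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (order:", paste(x$order, collapse = " > "), ")\n")
  cat(sprintf("samples: %d in, %d removed (call rate), %d out\n",
              x$n_samples_in, x$samples_removed_call_rate, x$n_samples_out))
  cat(sprintf(paste0("SNPs: %d in; removed: %d non-autosomal, %d call rate, ",
                     "%d MAF, %d HWE; %d out\n"),
              x$n_snps_in, x$snps_removed_nonautosomal,
              x$snps_removed_call_rate, x$snps_removed_maf,
              x$snps_removed_hwe, x$n_snps_out))
  invisible(x)
}

#' Write a QC report as CSV
#'
#' @param report a `qc_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    rule = c("samples_in", "samples_removed_call_rate", "samples_out",
             "snps_in", "snps_removed_nonautosomal", "snps_removed_call_rate",
             "snps_removed_maf", "snps_removed_hwe", "snps_out"),
    count = c(report$n_samples_in, report$samples_removed_call_rate,
              report$n_samples_out, report$n_snps_in,
              report$snps_removed_nonautosomal, report$snps_removed_call_rate,
              report$snps_removed_maf, report$snps_removed_hwe,
              report$n_snps_out))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
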