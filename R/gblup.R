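#' Genomic relationship matrix (Yang et al. style)
#'
#' Builds the marker-based realized relationship matrix. Off-diagonals are
#' the average over markers of \eqn{(x_{ij} - 2p_i)(x_{ik} - 2p_i) /
#' (2 p_i (1 - p_i))}; diagonals use the bias-adjusted form
#' \eqn{1 + \frac{1}{N}\sum_i (x_{ij}^2 - (1 + 2p_i) x_{ij} + 2p_i^2) /
#' (2 p_i (1 - p_i))}. Allele frequencies default to the sample analysed
#' (reference plus validation individuals), which is the recommended
#' pooled centering for multi-breed analyses.
#'
#' @param panel a [genotype_panel()] with complete genotypes for the
#'   selected individuals.
#' @param individuals optional ids/indices of the individuals to include.
#' @param markers optional marker indices; every included marker must be
#'   polymorphic in the selected sample (or in `freq` if supplied).
#' @param freq optional allele-frequency vector (one per selected marker)
#'   overriding sample frequencies, e.g. frequencies from a wider
#'   reference panel.
#' @return an object of class `grm`: list with the relationship matrix
#'   `G` (dimnames = individual ids), `ids`, `n_markers`, and `freq`.
#' @export
compute_grm <- function(panel, individuals = NULL, markers = NULL, freq = NULL) {
  X <- dosage(panel, individuals, markers)
  if (anyNA(X)) stop("GRM requires complete genotypes (no missing dosages)")
  storage.mode(X) <- "double"
  m <- ncol(X)
  p <- if (is.null(freq)) colMeans(X) / 2 else freq
  if (length(p) != m) stop("'freq' must have one entry per marker")
  fixed <- which(p <= 0 | p >= 1)
  if (length(fixed))
    stop("monomorphic marker(s) in GRM sample: ",
         paste(utils::head(colnames(X)[fixed], 5), collapse = ", "),
         if (length(fixed) > 5) sprintf(" (and %d more)", length(fixed) - 5))
  het <- 2 * p * (1 - p)
  a <- 1 / het
  # Yang et al. diagonal, computed from raw dosages before standardizing
  dg <- 1 + (as.vector((X * X) %*% a) - as.vector(X %*% ((1 + 2 * p) * a)) +
               sum(2 * p^2 * a)) / m
  Z <- X - rep(2 * p, each = nrow(X))
  Z <- Z * rep(1 / sqrt(het), each = nrow(X))
  G <- tcrossprod(Z) / m
  diag(G) <- dg
  structure(list(G = G, ids = rownames(X), n_markers = m, freq = p),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$ids), "individuals,", x$n_markers, "markers; ",
      sprintf("mean diagonal %.3f\n", mean(diag(x$G))))
  invisible(x)
}

chol_solve <- function(ch, b) backsolve(ch, backsolve(ch, b, transpose = TRUE))

#' Fit a GBLUP model
#'
#' Genomic best linear unbiased prediction: the mixed model
#' \eqn{y = Xb + g + e} with \eqn{g \sim N(0, G \sigma_g^2)} (G the
#' genomic relationship matrix) and \eqn{e \sim N(0, I \sigma_e^2)}, fitted
#' on the reference individuals. Writing \eqn{\lambda = \sigma_e^2 /
#' \sigma_g^2}, fixed effects are estimated by generalized least squares
#' and breeding values by
#' \eqn{\hat g = G_{\cdot r} (G_{rr} + \lambda I)^{-1} (y - X\hat b)},
#' which for validation individuals is genomic regression on the
#' reference. A small ridge is added to the GRM diagonal for numerical
#' stability (block-resampled individuals can be near-duplicates); the
#' solution is then exactly the joint mixed-model-equation solution for
#' the ridged GRM.
#'
#' @param formula model formula for the fixed effects, e.g. `y ~ 1`
#'   (overall mean) or `y ~ breed` (mean and breed) for multi-breed
#'   references. The response must be a column of `data`.
#' @param data data frame with one row per individual; matched to the GRM
#'   by a column `id` (or row names). Phenotypes must be present (non-NA)
#'   for all reference individuals.
#' @param grm a [compute_grm()] object covering reference and validation.
#' @param reference ids of the reference (training) individuals.
#' @param validation ids to predict; defaults to all GRM individuals not
#'   in the reference.
#' @param lambda variance ratio \eqn{\sigma_e^2/\sigma_g^2}; defaults to
#'   `(1 - h2) / h2` when `h2` is given. One of `lambda`/`h2` is required
#'   (use [estimate_variances_reml()] to estimate it from data).
#' @param h2 heritability from which to derive `lambda`.
#' @param ridge relative ridge added to the GRM diagonal
#'   (`ridge * mean(diag(G_rr))`).
#' @return an object of class `gblup` with components `coefficients`,
#'   `gebv` (named vector over reference then validation individuals),
#'   `fitted.values`, `residuals` (reference scale), `lambda`,
#'   `reference`, `validation` and the model frame bookkeeping. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`.
#' @export
gblup <- function(formula, data, grm, reference, validation = NULL,
                  lambda = NULL, h2 = NULL, ridge = 1e-6) {
  stopifnot(inherits(grm, "grm"))
  if (is.null(lambda)) {
    if (is.null(h2)) stop("supply 'lambda' or 'h2'")
    if (h2 <= 0 || h2 >= 1) stop("'h2' must lie in (0, 1)")
    lambda <- (1 - h2) / h2
  }
  if (lambda <= 0) stop("'lambda' must be positive")
  ids <- grm$ids
  if (!"id" %in% names(data)) data$id <- rownames(data)
  rid <- match(reference, ids)
  if (anyNA(rid)) stop("reference ids missing from the GRM")
  if (is.null(validation)) validation <- setdiff(ids, reference)
  vid <- match(validation, ids)
  if (anyNA(vid)) stop("validation ids missing from the GRM")
  if (length(intersect(reference, validation)))
    stop("reference and validation must be disjoint")

  drow <- match(reference, data$id)
  if (anyNA(drow)) stop("phenotype rows missing for some reference ids")
  mf <- stats::model.frame(formula, data[drow, , drop = FALSE])
  y <- as.numeric(stats::model.response(mf))
  if (anyNA(y)) stop("reference phenotypes contain NA")
  X <- stats::model.matrix(formula, mf)

  sol <- gblup_core(grm, rid, vid, X, y, lambda, ridge)
  structure(
    list(call = match.call(), formula = formula,
         coefficients = sol$b, gebv = sol$gebv, alpha = sol$alpha,
         lambda = lambda, ridge_eps = sol$eps,
         fitted.values = sol$fitted, residuals = sol$resid,
         reference = reference, validation = validation,
         grm = grm, y = y, X = X),
    class = "gblup")
}

# Shared solver. rid/vid: integer indices into grm$ids.
gblup_core <- function(grm, rid, vid, X, y, lambda, ridge, chol_cache = NULL) {
  Grr <- grm$G[rid, rid, drop = FALSE]
  eps <- ridge * mean(diag(Grr))
  if (is.null(chol_cache)) {
    M <- Grr
    diag(M) <- diag(M) + eps + lambda
    ch <- tryCatch(chol(M),
                   error = function(e) stop("GBLUP system not positive definite: ",
                                            conditionMessage(e)))
  } else ch <- chol_cache
  ViX <- chol_solve(ch, X)
  XtViX <- crossprod(X, ViX)
  qrX <- qr(XtViX)
  if (qrX$rank < ncol(X)) stop("singular fixed-effect design")
  b <- drop(solve(qrX, crossprod(X, chol_solve(ch, y))))
  names(b) <- colnames(X)
  alpha <- drop(chol_solve(ch, y - drop(X %*% b)))
  g_ref <- drop(Grr %*% alpha) + eps * alpha
  g_val <- if (length(vid)) drop(grm$G[vid, rid, drop = FALSE] %*% alpha) else numeric(0)
  gebv <- c(g_ref, g_val)
  names(gebv) <- grm$ids[c(rid, vid)]
  fitted <- unname(drop(X %*% b)) + g_ref
  list(b = b, alpha = alpha, gebv = gebv, eps = eps,
       fitted = fitted, resid = y - fitted, chol = ch)
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit:", length(x$reference), "reference,",
      length(x$validation), "validation individuals; lambda =",
      format(x$lambda, digits = 4), "\n")
  cat("fixed effects:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  out <- list(
    n_reference = length(object$reference),
    n_validation = length(object$validation),
    lambda = object$lambda,
    h2_implied = 1 / (1 + object$lambda),
    coefficients = object$coefficients,
    gebv_sd = stats::sd(object$gebv),
    resid_sd = stats::sd(object$residuals))
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat(sprintf("GBLUP: %d reference / %d validation individuals\n",
              x$n_reference, x$n_validation))
  cat(sprintf("lambda = %.4g (implied h2 = %.3f)\n", x$lambda, x$h2_implied))
  cat("fixed effects:\n"); print(x$coefficients)
  cat(sprintf("sd(GEBV) = %.4g, sd(residual) = %.4g\n", x$gebv_sd, x$resid_sd))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$coefficients

#' @export
fitted.gblup <- function(object, ...) object$fitted.values

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' Predict genomic breeding values
#'
#' GEBVs for individuals covered by the fit's GRM; individuals outside
#' the original validation set are predicted by genomic regression on the
#' reference, `G_new,r %*% alpha`.
#'
#' @param object a [gblup()] fit.
#' @param ids individual ids (default: the fit's validation set).
#' @param ... unused.
#' @return named numeric vector of GEBVs.
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  if (is.null(ids)) ids <- object$validation
  known <- ids %in% names(object$gebv)
  out <- numeric(length(ids))
  out[known] <- object$gebv[ids[known]]
  if (any(!known)) {
    idx <- match(ids[!known], object$grm$ids)
    if (anyNA(idx)) stop("id(s) not covered by the GRM")
    rid <- match(object$reference, object$grm$ids)
    out[!known] <- drop(object$grm$G[idx, rid, drop = FALSE] %*% object$alpha)
  }
  names(out) <- ids
  out
}

#' @export
plot.gblup <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values, xlab = "phenotype (reference)",
                 ylab = "fitted (Xb + GEBV)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' EM-REML variance components for the GBLUP model
#'
#' Estimates \eqn{(\sigma_g^2, \sigma_e^2)} in \eqn{y = Xb + g + e},
#' \eqn{g \sim N(0, G\sigma_g^2)}, by expectation-maximisation REML.
#' The GRM is eigendecomposed once so each iteration costs
#' \eqn{O(n p^2)}. Iterates until the relative change of both components
#' falls below `tol` or `max_iter` is reached (with a warning).
#'
#' @param y phenotype vector (one per GRM individual, same order as
#'   `grm$ids` unless `ids` is given).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param grm a [compute_grm()] object.
#' @param ids optional ids matching `y` to the GRM.
#' @param tol relative convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param ridge relative ridge added to the GRM diagonal before
#'   eigendecomposition.
#' @return list with `sigma_g2`, `sigma_e2`, `h2`, `iterations`,
#'   `converged`.
#' @export
estimate_variances_reml <- function(y, X = NULL, grm, ids = NULL,
                                    tol = 1e-6, max_iter = 200L,
                                    ridge = 1e-6) {
  stopifnot(inherits(grm, "grm"))
  idx <- if (is.null(ids)) seq_along(grm$ids) else match(ids, grm$ids)
  if (anyNA(idx)) stop("ids missing from GRM")
  n <- length(idx)
  if (n < 30L) stop("REML needs at least 30 observations")
  if (length(y) != n) stop("length(y) must match the individuals analysed")
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  G <- grm$G[idx, idx]
  diag(G) <- diag(G) + ridge * mean(diag(G))
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)

  vy <- stats::var(y)
  sg <- max(vy / 2, 1e-10)
  se <- max(vy / 2, 1e-10)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    lam <- se / sg
    u <- lam / (d + lam)              # diag(I - T)
    t_ <- d / (d + lam)               # diag(T)
    S <- crossprod(Xt, Xt * u)
    b <- drop(solve(S, crossprod(Xt, u * yt)))
    r <- yt - drop(Xt %*% b)
    gt <- t_ * r
    # tr(G^-1 Cgg), Cgg = se * [T + T Xt S^-1 Xt' T]
    TX <- Xt * t_
    tr_gc <- se * (sum(t_ / d) + sum((TX %*% solve(S)) * TX / d))
    sg_new <- (sum(gt^2 / d) + tr_gc) / n
    se_new <- (sum(yt^2) - sum(b * crossprod(Xt, yt)) - sum(gt * yt)) / (n - p)
    se_new <- max(se_new, 1e-12)
    sg_new <- max(sg_new, 1e-12)
    delta <- max(abs(sg_new - sg) / max(sg, 1e-12),
                 abs(se_new - se) / max(se, 1e-12))
    sg <- sg_new; se <- se_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning last iterate")
  list(sigma_g2 = sg, sigma_e2 = se, h2 = sg / (sg + se),
       iterations = it, converged = converged)
}
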