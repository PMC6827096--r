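#' QTL architecture strategies
#'
#' Four preset genetic architectures for trait simulation, differing in
#' the total number of QTL and the mix of small / medium / large effect
#' classes (effects drawn from N(0, 0.0001), N(0, 0.001) and N(0, 0.01)
#' times the nominal effect-scale variance, respectively):
#'
#' * `"I"`   — 100 QTL, all large;
#' * `"II"`  — 2000 QTL: 1361 small, 614 medium, 25 large;
#' * `"III"` — 5000 QTL: 4595 small, 390 medium, 15 large;
#' * `"IV"`  — 10000 QTL, all small.
#'
#' @param name one of `"I"`, `"II"`, `"III"`, `"IV"`, or `"custom"` with
#'   the class counts given explicitly.
#' @param n_small,n_medium,n_large class counts for a custom strategy.
#' @return an object of class `architecture_strategy`.
#' @export
architecture_strategy <- function(name = c("I", "II", "III", "IV", "custom"),
                                  n_small = 0L, n_medium = 0L, n_large = 0L) {
  name <- match.arg(name)
  preset <- switch(name,
    I   = c(0L, 0L, 100L),
    II  = c(1361L, 614L, 25L),
    III = c(4595L, 390L, 15L),
    IV  = c(10000L, 0L, 0L),
    custom = as.integer(c(n_small, n_medium, n_large)))
  if (any(preset < 0L) || sum(preset) < 1L)
    stop("class counts must be non-negative and sum to at least 1")
  structure(list(name = name, n_small = preset[1], n_medium = preset[2],
                 n_large = preset[3], n_qtl_total = sum(preset)),
            class = "architecture_strategy")
}

#' @export
print.architecture_strategy <- function(x, ...) {
  cat(sprintf("architecture_strategy %s: %d QTL (%d small, %d medium, %d large)\n",
              x$name, x$n_qtl_total, x$n_small, x$n_medium, x$n_large))
  invisible(x)
}

# per-class effect variance multipliers (x nominal sigma_g2)
EFFECT_CLASS_VAR <- c(small = 1e-4, medium = 1e-3, large = 1e-2)

#' Sample a QTL set
#'
#' Draws QTL positions uniformly without replacement from the panel's
#' polymorphic markers and additive allele-substitution effects from
#' zero-mean normals with class-specific variances `c * sigma_g2`,
#' `c = 0.0001 / 0.001 / 0.01` for small / medium / large. The nominal
#' effect-scale variance `sigma_g2` is 1; the genetic variance the QTL
#' actually create in a population is the realized `var(tbv)`, which
#' [simulate_phenotypes()] uses to scale environmental noise.
#'
#' @param panel a [genotype_panel()].
#' @param strategy an [architecture_strategy()].
#' @param sigma_g2 nominal effect-scale variance.
#' @param seed optional seed.
#' @param polymorphic optional precomputed indices of polymorphic
#'   markers (avoids rescanning the panel in repeated calls).
#' @return an object of class `qtl_set`: data frame with columns
#'   `marker` (index into the panel), `id`, `effect`, `class`.
#' @export
sample_qtl <- function(panel, strategy, sigma_g2 = 1, seed = NULL,
                       polymorphic = NULL) {
  stopifnot(inherits(strategy, "architecture_strategy"))
  if (!is.null(seed)) set.seed(seed)
  poly <- if (is.null(polymorphic)) {
    p <- allele_freq(panel)
    which(p > 0 & p < 1)
  } else polymorphic
  if (length(poly) < strategy$n_qtl_total)
    stop("panel has too few polymorphic markers for ",
         strategy$n_qtl_total, " QTL")
  idx <- sample(poly, strategy$n_qtl_total)
  cls <- rep(c("small", "medium", "large"),
             c(strategy$n_small, strategy$n_medium, strategy$n_large))
  eff <- stats::rnorm(strategy$n_qtl_total, 0,
                      sqrt(EFFECT_CLASS_VAR[cls] * sigma_g2))
  out <- data.frame(marker = idx, id = panel$map$id[idx], effect = eff,
                    class = cls, stringsAsFactors = FALSE)
  class(out) <- c("qtl_set", "data.frame")
  attr(out, "strategy") <- strategy$name
  attr(out, "sigma_g2") <- sigma_g2
  out
}

#' True breeding values
#'
#' \eqn{TBV_i = \sum_j x_{ij} a_j} with dosage coded 0/1/2. Computed in
#' blocks of individuals to bound memory on large panels.
#'
#' @param panel a [genotype_panel()].
#' @param qtl a [sample_qtl()] object (or data frame with `marker` and
#'   `effect`).
#' @return named numeric vector of TBVs, one per individual.
#' @export
compute_tbv <- function(panel, qtl) {
  if (any(qtl$marker < 1L | qtl$marker > n_markers(panel)))
    stop("QTL indices outside the panel")
  n <- n_ind(panel)
  out <- numeric(n)
  step <- 2000L
  for (s in seq(1L, n, by = step)) {
    idx <- s:min(s + step - 1L, n)
    X <- dosage(panel, individuals = idx, markers = qtl$marker)
    storage.mode(X) <- "double"
    out[idx] <- drop(X %*% qtl$effect)
  }
  names(out) <- panel$ids
  out
}

#' Simulate phenotypes at a target heritability
#'
#' Adds i.i.d. normal environmental deviates with variance
#' \eqn{V_g (1 - h^2) / h^2}, where \eqn{V_g} is the realized genetic
#' variance: the variance of `tbv` in the simulated population, or — when
#' `groups` is supplied — the mean within-group variance. The latter is
#' appropriate for strongly structured multi-breed panels, where the
#' pooled variance contains a between-breed component and pooled scaling
#' would deflate the within-breed heritability that genomic prediction
#' operates on.
#'
#' @param tbv numeric vector of true breeding values.
#' @param h2 target heritability in (0, 1).
#' @param groups optional grouping factor (e.g. breed labels) for
#'   within-group variance scaling.
#' @param seed optional seed.
#' @return an object of class `trait_sim`: data frame with columns `id`,
#'   `tbv`, `env`, `y` (`y = tbv + env` exactly); attributes `h2`, `Vg`
#'   (the variance used for scaling) and `var_env`.
#' @export
simulate_phenotypes <- function(tbv, h2, groups = NULL, seed = NULL) {
  if (h2 <= 0 || h2 >= 1) stop("'h2' must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  vg <- if (is.null(groups)) stats::var(tbv)
        else mean(tapply(tbv, groups, stats::var))
  if (!is.finite(vg) || vg <= 0)
    stop("var(tbv) is zero; cannot scale environmental noise")
  ve <- vg * (1 - h2) / h2
  env <- stats::rnorm(length(tbv), 0, sqrt(ve))
  out <- data.frame(id = if (is.null(names(tbv))) seq_along(tbv) else names(tbv),
                    tbv = as.numeric(tbv), env = env,
                    y = as.numeric(tbv) + env, stringsAsFactors = FALSE)
  class(out) <- c("trait_sim", "data.frame")
  attr(out, "h2") <- h2
  attr(out, "Vg") <- vg
  attr(out, "var_env") <- ve
  out
}
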