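# Dense joint mixed-model-equation oracle: all animals carry a breeding
# value, only reference animals carry records. Independent of the
# package's solver path.
mme_oracle <- function(grm, eps, y, X, ref_idx, lambda) {
  n <- length(grm$ids)
  Gt <- grm$G
  diag(Gt) <- diag(Gt) + eps
  W <- matrix(0, length(ref_idx), n)
  W[cbind(seq_along(ref_idx), ref_idx)] <- 1
  Ginv <- solve(Gt)
  C <- rbind(cbind(crossprod(X), t(X) %*% W),
             cbind(t(W) %*% X, crossprod(W) + lambda * Ginv))
  rhs <- c(crossprod(X, y), crossprod(W, y))
  sol <- solve(C, rhs)
  list(b = sol[seq_len(ncol(X))], g = sol[-seq_len(ncol(X))])
}

test_that("GRM entries match the hand-computed Yang formulas", {
  # single marker, dosages (0, 2), p = 0.5: off-diagonal (0-1)(2-1)/0.5 = -2
  p1 <- toy_panel(rbind(0L, 0L, 1L, 1L))
  g1 <- compute_grm(p1)
  expect_equal(g1$G[1, 2], -2)

  # two identical individuals, 3 markers, forced p = 0.5: off-diagonal
  # equals each one's VanRaden-style self-similarity term sum (x-1)^2/0.5 / 3
  hap <- rbind(c(1, 0, 1), c(1, 0, 0),
               c(1, 0, 1), c(1, 0, 0))  # dosages (2,0,1) twice
  p2 <- toy_panel(hap)
  g2 <- compute_grm(p2, freq = rep(0.5, 3))
  self_sim <- mean((c(2, 0, 1) - 1)^2 / 0.5)
  expect_equal(g2$G[1, 2], self_sim)

  # monomorphic marker is an explicit failure naming the marker
  p3 <- toy_panel(rbind(c(1, 1), c(1, 0), c(1, 1), c(1, 1)))
  expect_error(compute_grm(p3), "monomorphic.*m1")
})

test_that("GRM of an HWE sample has mean diagonal near 1 and centers to zero", {
  diags <- vapply(1:10, function(s) {
    p <- hwe_panel(500, runif(300, 0.1, 0.9), seed = s)
    mean(diag(compute_grm(p)$G))
  }, numeric(1))
  expect_true(all(diags > 0.95 & diags < 1.05))
  # centering identity with sample frequencies: rows/cols sum to zero
  p <- hwe_panel(80, runif(150, 0.1, 0.9), seed = 99)
  G <- compute_grm(p)$G
  offsum <- sum(G) - sum(diag(G))
  # off-diagonal part of Z Z' sums to -sum of diag(Z Z'); compare against
  # the standardized-dosage cross-product directly
  X <- dosage(p); storage.mode(X) <- "double"
  pf <- colMeans(X) / 2
  Z <- scale(X, center = 2 * pf, scale = sqrt(2 * pf * (1 - pf)))
  ZZ <- tcrossprod(Z) / ncol(X)
  expect_lt(abs(sum(ZZ)) / length(G), 1e-8)
  expect_equal(offsum, sum(ZZ) - sum(diag(ZZ)), tolerance = 1e-8)
})

test_that("solver equals the dense joint-MME oracle at n <= 100", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 60
    p <- hwe_panel(n, runif(120, 0.1, 0.9), breed = rep(c("A", "B"), n / 2),
                   seed = seed + 100)
    grm <- compute_grm(p)
    ref <- p$ids[1:40]
    val <- p$ids[41:60]
    y <- rnorm(40) + 2 * (p$breed[1:40] == "B")
    dat <- data.frame(id = ref, y = y, breed = p$breed[1:40])
    fit <- gblup(y ~ breed, dat, grm, reference = ref, validation = val,
                 h2 = 0.5)
    X <- model.matrix(~breed, dat)
    orc <- mme_oracle(grm, fit$ridge_eps, y, X, match(ref, grm$ids), 1)
    expect_equal(unname(fit$gebv[c(ref, val)]),
                 as.numeric(orc$g)[match(c(ref, val), grm$ids)],
                 tolerance = 1e-8)
    expect_equal(unname(fit$coefficients), as.numeric(orc$b),
                 tolerance = 1e-8)
  }
})

test_that("shrinkage limit and translation invariance hold", {
  set.seed(5)
  p <- hwe_panel(50, runif(100, 0.2, 0.8), seed = 55)
  grm <- compute_grm(p)
  ref <- p$ids[1:35]
  y <- rnorm(35, mean = 3)
  dat <- data.frame(id = ref, y = y)
  # lambda -> Inf: GEBVs -> 0 and fixed effect -> OLS (here the mean)
  big <- gblup(y ~ 1, dat, grm, reference = ref, lambda = 1e10)
  expect_lt(max(abs(big$gebv)), 1e-6)
  expect_equal(unname(big$coefficients[1]), mean(y), tolerance = 1e-6)
  # adding a constant shifts the intercept, not the GEBVs
  fit1 <- gblup(y ~ 1, dat, grm, reference = ref, h2 = 0.4)
  dat2 <- dat; dat2$y <- dat$y + 7
  fit2 <- gblup(y ~ 1, dat2, grm, reference = ref, h2 = 0.4)
  expect_equal(fit1$gebv, fit2$gebv, tolerance = 1e-10)
  expect_equal(unname(fit2$coefficients[1] - fit1$coefficients[1]), 7,
               tolerance = 1e-10)
})

test_that("gblup object methods are coherent", {
  set.seed(6)
  p <- hwe_panel(40, runif(80, 0.2, 0.8), seed = 66)
  grm <- compute_grm(p)
  ref <- p$ids[1:30]
  dat <- data.frame(id = ref, y = rnorm(30))
  fit <- gblup(y ~ 1, dat, grm, reference = ref, h2 = 0.5)
  expect_s3_class(fit, "gblup")
  expect_equal(unname(fitted(fit) + residuals(fit)), dat$y)
  # residual identity of the mixed model: y - Xb - g = lambda * alpha
  expect_equal(unname(residuals(fit)), fit$lambda * fit$alpha)
  expect_equal(unname(predict(fit)), unname(fit$gebv[fit$validation]))
  expect_equal(unname(predict(fit, ref[1:3])), unname(fit$gebv[ref[1:3]]))
  expect_output(print(fit), "GBLUP fit")
  expect_output(print(summary(fit)), "implied h2")
  expect_error(gblup(y ~ 1, dat, grm, reference = ref), "lambda")
})

test_that("EM-REML recovers heritability and scales exactly with the data", {
  set.seed(7)
  # direct simulation from the GRM: g ~ N(0, G), e ~ N(0, I * (1-h2)/h2)
  p <- hwe_panel(300, runif(400, 0.1, 0.9), seed = 77)
  grm <- compute_grm(p)
  eg <- eigen(grm$G, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  h2s <- vapply(1:5, function(s) {
    set.seed(s)
    g <- drop(L %*% rnorm(300))
    y <- g + rnorm(300, 0, sqrt(var(g) * 0.4 / 0.6))
    suppressWarnings(estimate_variances_reml(y, grm = grm))$h2
  }, numeric(1))
  expect_gt(mean(h2s), 0.5)
  expect_lt(mean(h2s), 0.7)

  # y = Xb exactly: genetic variance collapses
  yx <- rep(2.5, 300)
  fit0 <- suppressWarnings(
    estimate_variances_reml(yx + 0.01 * rnorm(300), grm = grm))
  expect_lt(fit0$h2, 0.2)

  # estimates are invariant to phenotype rescaling (h2) and respond
  # quadratically in the components
  set.seed(8)
  y <- rnorm(100)
  psub <- hwe_panel(100, runif(200, 0.1, 0.9), seed = 88)
  g1 <- compute_grm(psub)
  est1 <- suppressWarnings(estimate_variances_reml(y, grm = g1))
  est3 <- suppressWarnings(estimate_variances_reml(3 * y, grm = g1))
  expect_equal(est3$h2, est1$h2, tolerance = 1e-4)
  expect_equal(est3$sigma_e2, 9 * est1$sigma_e2, tolerance = 1e-3)
  expect_equal(est3$sigma_g2, 9 * est1$sigma_g2, tolerance = 1e-2)
})
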