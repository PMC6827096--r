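# shared small world for scenario tests: 4 breeds x 120 individuals
scen_world <- local({
  env <- new.env()
  function() {
    if (is.null(env$sim)) {
      cfg <- founder_config(n_breeds = 4, groups = c(1, 1, 2, 2),
                            founders_per_breed = 12, n_markers = 800,
                            n_chr = 2, ne_base = 60, gen_base = 25,
                            ne_group = 40, gen_group = 12, ne_breed = 25,
                            gen_breed = 8, seed = 50)
      fp <- generate_founders(cfg)
      env$sim <- expand_panel(fp, resample_config(block_size_markers = 100,
                                                  n_per_breed = 120, seed = 51))
    }
    env$sim
  }
})

test_that("accuracy is the Pearson correlation with the stated edge cases", {
  expect_equal(accuracy(1:10, 1:10), 1)
  expect_equal(accuracy(1:10, -(1:10)), -1)
  g <- c(1, 2, 3, 4); t_ <- c(1.1, 1.9, 3.2, 3.8)
  manual <- sum((g - mean(g)) * (t_ - mean(t_))) /
    sqrt(sum((g - mean(g))^2) * sum((t_ - mean(t_))^2))
  expect_equal(accuracy(g, t_), manual)
  expect_true(is.na(accuracy(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(accuracy(c(1, 2), c(1, 2))))
})

test_that("splits honour quotas and disjointness for each design", {
  sim <- scen_world()
  # single breed: quota + remainder validation, disjoint
  sp <- scenario_spec("B01", n_reference = 90, validation_per_breed = 30,
                      seed = 1)
  s <- make_splits(sp, sim)
  expect_equal(length(s$reference), 90)
  expect_equal(length(s$validation$B01), 30)
  expect_equal(length(intersect(s$reference, s$validation$B01)), 0)

  # combined design: equal per-breed quota
  spc <- scenario_spec(sprintf("B%02d", 1:4), design = "combined",
                       n_reference = 80, validation_per_breed = 20, seed = 2)
  sc <- make_splits(spc, sim)
  ref_breed <- sim$breed[match(sc$reference, sim$ids)]
  expect_equal(as.vector(table(ref_breed)), rep(20L, 4))
  for (b in names(sc$validation))
    expect_equal(length(intersect(sc$reference, sc$validation[[b]])), 0)

  # three-breed quota: n_reference / 3 each
  sp3 <- scenario_spec(c("B01", "B02", "B03"), n_reference = 90, seed = 3)
  expect_equal(sp3$quota, 30)
  expect_error(scenario_spec(c("B01", "B02", "B03"), n_reference = 100),
               "divide equally")
  expect_error(make_splits(scenario_spec("B01", n_reference = 500, seed = 1),
                           sim), "quota")
})

test_that("grid accuracies rise with heritability and vanish without signal", {
  sim <- scen_world()
  tg <- simulate_traits(sim, strategies = "I", h2 = c(0.05, 0.3, 0.6),
                        n_replicates = 4, seed = 60)
  sp <- scenario_spec("B01", n_reference = 90, validation_per_breed = 30,
                      strategies = "I", h2 = c(0.05, 0.3, 0.6),
                      n_replicates = 4, seed = 61)
  res <- run_grid(sp, sim, tg)
  sm <- summary(res)
  sm <- sm[order(sm$h2), ]
  expect_true(all(diff(sm$mean_accuracy) > 0))

  # no-signal limit: pure-noise phenotypes predict TBV with accuracy ~ 0
  set.seed(62)
  b1 <- sim$ids[sim$breed == "B01"]
  ref <- b1[1:90]; val <- b1[91:120]
  p1 <- allele_freq(sim, individuals = b1)
  grm <- compute_grm(sim, individuals = b1,
                     markers = which(p1 > 0 & p1 < 1))
  tbv <- tg$traits$I[[1]]$tbv
  accs <- vapply(1:6, function(r) {
    fit <- gblup(y ~ 1, data.frame(id = ref, y = rnorm(90)), grm,
                 reference = ref, validation = val, h2 = 0.3)
    accuracy(predict(fit), tbv[match(val, names(tbv))])
  }, numeric(1))
  expect_lt(abs(mean(accs)), 0.2)
  expect_true(all(abs(accs) < 0.5))
})

test_that("reruns under the same master seed are bit-identical", {
  sim <- scen_world()
  tg1 <- simulate_traits(sim, strategies = "I", h2 = 0.6, n_replicates = 2,
                         seed = 70)
  tg2 <- simulate_traits(sim, strategies = "I", h2 = 0.6, n_replicates = 2,
                         seed = 70)
  sp <- scenario_spec(c("B01", "B03"), n_reference = 80,
                      validation_per_breed = 20, foreign_validation = TRUE,
                      strategies = "I", h2 = 0.6, n_replicates = 2, seed = 71)
  r1 <- run_grid(sp, sim, tg1)
  r2 <- run_grid(sp, sim, tg2)
  expect_identical(r1$accuracy, r2$accuracy)
  # every grid cell present
  expect_equal(nrow(r1), 2 * 4)  # 2 replicates x 4 validation breeds
  expect_true(all(abs(r1$accuracy) <= 1))
})

test_that("multi-breed references use breed fixed effects and score foreigners", {
  sim <- scen_world()
  tg <- simulate_traits(sim, strategies = "I", h2 = 0.6, n_replicates = 3,
                        seed = 80)
  sp <- scenario_spec(c("B01", "B02"), n_reference = 120,
                      validation_per_breed = 30, foreign_validation = TRUE,
                      strategies = "I", h2 = 0.6, n_replicates = 3, seed = 81)
  res <- run_grid(sp, sim, tg)
  sm <- summary(res)
  acc_in <- sm$mean_accuracy[sm$in_reference]
  acc_out <- sm$mean_accuracy[!sm$in_reference]
  expect_gt(acc_in, acc_out)
})
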