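test_that("PCA separates diverged breeds and respects invariances", {
  # two breeds drifted apart: PC1 separates them with no overlap
  cfg <- founder_config(n_breeds = 2, groups = c(1, 2), founders_per_breed = 20,
                        n_markers = 400, n_chr = 2, ne_base = 60, gen_base = 20,
                        ne_group = 30, gen_group = 25, ne_breed = 30,
                        gen_breed = 5, seed = 31)
  p <- generate_founders(cfg)
  pc <- panel_pca(p, n_components = 2)
  s1 <- pc$scores[pc$breed == "B01", 1]
  s2 <- pc$scores[pc$breed == "B02", 1]
  expect_true(max(min(s1), min(s2)) > min(max(s1), max(s2)) ||
                min(s1) > max(s2) || min(s2) > max(s1))

  # duplicating every individual leaves score geometry unchanged up to sign
  ph <- hwe_panel(15, runif(50, 0.2, 0.8), seed = 32)
  dup <- bind_panels(ph, genotype_panel(ph$haplotypes, ph$map,
                                        paste0("d", ph$ids), ph$breed))
  pc1 <- panel_pca(ph, 2)
  pc2 <- panel_pca(dup, 2)
  al <- cor(pc1$scores[, 1], pc2$scores[1:15, 1])
  expect_equal(abs(al), 1, tolerance = 1e-8)

  # rank-1 dosage pattern: one component explains everything
  hap <- rbind(c(0, 0, 0), c(0, 0, 0),
               c(1, 1, 1), c(0, 0, 0),
               c(1, 1, 1), c(1, 1, 1))
  pr <- panel_pca(toy_panel(hap), 1)
  expect_equal(pr$sdev[1]^2 / sum(pr$sdev^2), 1, tolerance = 1e-12)

  expect_error(panel_pca(toy_panel(rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1)))),
               "polymorphic")
})

test_that("k-means grouping recovers configured groups and edge cases", {
  p <- generate_founders(small_founder_config(seed = 33, n_markers = 600))
  pc <- panel_pca(p, 5)
  grp <- kmeans_groups(pc, k = 3, seed = 1)
  truth <- rep(1:3, each = 2)
  names(truth) <- sprintf("B%02d", 1:6)
  # same partition (cluster ids may be permuted)
  expect_equal(length(unique(paste(grp, truth))), 3)

  # k = number of breeds: every breed its own group
  grp_all <- kmeans_groups(pc, k = 6, seed = 1)
  expect_equal(length(unique(grp_all)), 6)
  expect_error(kmeans_groups(pc, k = 7), "exceeds")

  # two copies of the same breed always co-assigned
  ph <- hwe_panel(10, runif(80, 0.2, 0.8), seed = 34)
  twin <- bind_panels(
    genotype_panel(ph$haplotypes, ph$map, paste0("a", 1:10), rep("A", 10)),
    genotype_panel(ph$haplotypes, ph$map, paste0("b", 1:10), rep("B", 10)),
    hwe_panel(10, runif(80, 0.2, 0.8), breed = rep("C", 10), seed = 35))
  g3 <- kmeans_groups(panel_pca(twin, 4), k = 2, seed = 2)
  expect_equal(g3[["A"]], g3[["B"]])
})

test_that("phase persistence is 1 on identical panels and symmetric", {
  p <- hwe_panel(20, runif(200, 0.2, 0.8), spacing = 500, seed = 36)
  bins <- phase_bins(small = c(5e3, 2.5e3), medium = c(2e4, 5e3),
                     large = c(5e4, 1e4))
  pp <- phase_persistence(p, p, bins)
  pop <- pp$n_pairs > 0
  expect_true(any(pop))
  expect_equal(pp$correlation[pop], rep(1, sum(pop)), tolerance = 1e-10)

  q <- hwe_panel(20, runif(200, 0.2, 0.8), spacing = 500, seed = 37)
  ab <- phase_persistence(p, q, bins)
  ba <- phase_persistence(q, p, bins)
  expect_equal(ab$correlation, ba$correlation, tolerance = 1e-12)
})

test_that("resampled panels keep phase; scrambled panels lose it", {
  set.seed(38)
  cfg <- founder_config(n_breeds = 1, groups = 1, founders_per_breed = 25,
                        n_markers = 1500, n_chr = 3, ne_base = 80,
                        gen_base = 40, ne_group = 50, gen_group = 10,
                        ne_breed = 40, gen_breed = 10, seed = 38)
  p <- generate_founders(cfg)
  sim <- expand_breed(p, "B01", resample_config(block_size_markers = 300,
                                                n_per_breed = 600, seed = 39))
  bins <- phase_bins()
  pp <- phase_persistence(p, sim, bins)
  expect_gt(pp$correlation[1], 0.9)

  # destroying phase by permuting haplotypes per marker kills correlation
  H <- haplotypes(sim)
  for (j in seq_len(ncol(H))) H[, j] <- H[sample(nrow(H)), j]
  scr <- genotype_panel(H, sim$map, sim$ids, sim$breed)
  ps <- phase_persistence(p, scr, bins)
  pop <- which(ps$n_pairs > 50)
  expect_lt(max(abs(ps$correlation[pop])), 0.25)

  # empty bins are reported as missing, never zero
  sparse <- phase_bins(small = c(2, 1), medium = c(4, 2), large = c(6, 2))
  pe <- phase_persistence(p, sim, sparse)
  expect_true(all(is.na(pe$correlation[pe$n_pairs == 0])))
})

test_that("within-block phase beats across-block phase in resampled panels", {
  cfg <- founder_config(n_breeds = 1, groups = 1, founders_per_breed = 20,
                        n_markers = 1200, n_chr = 2, ne_base = 60,
                        gen_base = 30, ne_group = 40, gen_group = 5,
                        ne_breed = 30, gen_breed = 5, seed = 40)
  p <- generate_founders(cfg)
  # small blocks (~50 markers * ~4 kb = ~200 kb): distances < 100 kb are
  # mostly within-block, distances near 1 Mb always span boundaries
  sim <- expand_breed(p, "B01", resample_config(block_size_markers = 50,
                                                n_per_breed = 600, seed = 41))
  pp <- phase_persistence(p, sim, phase_bins())
  shortr <- pp$correlation[1]
  longr <- pp$correlation[nrow(pp)]
  expect_gt(shortr, longr)
})

test_that("phase bins validate and pair enumeration respects chromosomes", {
  b <- phase_bins()
  expect_true(all(diff(c(b$lower[1], b$upper)) > 0))
  expect_equal(nrow(b), 4 + 9 + 9)
  map <- data.frame(chr = c(1, 1, 2), id = c("a", "b", "c"),
                    bp = c(100, 200, 150), cm = c(0, 0, 0) , a1 = "A", a2 = "B")
  pr <- mosaicgp:::ld_pairs(map, 1e6)
  expect_equal(nrow(pr), 1)  # only the two chr-1 markers pair up
  expect_equal(pr$dist, 100)
})
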