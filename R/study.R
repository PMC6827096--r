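#' Run the full multi-breed reference-design study
#'
#' End-to-end experiment: generates a 10-breed synthetic founder panel
#' (25 founders per breed by default), expands every breed to 1,500
#' individuals by 500-marker block resampling, simulates traits for the
#' requested architecture strategies and heritabilities, recovers the
#' three breed groups by PCA + K-means, and evaluates GBLUP accuracy
#' under the classic reference designs:
#'
#' * within-breed: 1,200 reference / 300 validation per breed;
#' * across-breed: each breed in turn as a 1,200-individual reference,
#'   scored on 300 individuals from every other breed;
#' * combined: 120 individuals from each of the 10 breeds;
#' * three-breed within-group and cross-group references (400 each).
#'
#' All randomness derives from the single `seed`. The heavy inputs
#' (genotypes, traits) are shared across designs so the comparison is
#' paired.
#'
#' `study_founder_config()` is the default founder configuration of the
#' study: 25 founders per breed, and the marker count oversized (with
#' proportionally tightened spacing) so that after dropping markers that
#' drift to monomorphism across founders, the analysed panel carries
#' about 20,000 SNPs at about 4 kb mean spacing.
#'
#' @param seed master seed.
#' @param n_replicates trait replicates per grid cell.
#' @param strategies architecture strategies to simulate.
#' @param h2 heritabilities to simulate. The across-breed and three-breed
#'   designs are evaluated at `max(h2)` only.
#' @param founders optional [founder_config()] overriding the default
#'   study panel.
#' @param resample optional [resample_config()].
#' @param verbose print stage progress.
#' @return For `study_founder_config()`: the study's default
#'   [founder_config()]. For `run_study()`: list with elements `results`
#'   (all accuracy records),
#'   `summary` (aggregated means), `headline` (named list of the study's
#'   headline accuracies), `groups` (K-means breed grouping), and
#'   `panel_info`.
#' @export
run_study <- function(seed = 1, n_replicates = 10,
                      strategies = c("I", "II", "III", "IV"),
                      h2 = c(0.1, 0.3, 0.6),
                      founders = NULL, resample = NULL,
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 200)

  if (is.null(founders)) founders <- study_founder_config()
  founders$seed <- seeds[1]
  if (is.null(resample)) resample <- resample_config(seed = seeds[2])
  else resample$seed <- seeds[2]

  say("generating founders")
  fp <- generate_founders(founders)
  say("expanding breeds")
  sim <- expand_panel(fp, resample)
  breeds <- unique(sim$breed)
  say("simulating traits")
  traits <- simulate_traits(sim, strategies, h2, n_replicates,
                            seed = seeds[3])

  say("recovering breed groups")
  groups <- kmeans_groups(panel_pca(fp, 5), k = 3, seed = seeds[4])
  h_top <- max(h2)

  res <- list()
  say("within-breed designs")
  for (i in seq_along(breeds)) {
    sp <- scenario_spec(breeds[i], design = "within_breed",
                        strategies = strategies, h2 = h2,
                        n_replicates = n_replicates, seed = seeds[10 + i])
    res[[length(res) + 1L]] <- run_grid(sp, sim, traits)
  }
  say("across-breed (foreign validation) designs")
  for (i in seq_along(breeds)) {
    sp <- scenario_spec(breeds[i], design = "across_breed",
                        foreign_validation = TRUE,
                        strategies = strategies, h2 = h_top,
                        n_replicates = n_replicates, seed = seeds[30 + i])
    res[[length(res) + 1L]] <- run_grid(sp, sim, traits)
  }
  say("combined 10-breed design")
  spc <- scenario_spec(breeds, design = "combined_ten",
                       strategies = strategies, h2 = h2,
                       n_replicates = n_replicates, seed = seeds[51])
  res[[length(res) + 1L]] <- run_grid(spc, sim, traits)

  # three-breed references from the recovered grouping
  gsz <- table(groups)
  g3 <- names(gsz)[gsz == 3L]
  within_breeds <- if (length(g3)) sort(names(groups)[groups == as.integer(g3[1])])[1:3]
                   else sort(names(groups)[groups == as.integer(names(gsz)[1])])[1:3]
  cross_breeds <- vapply(sort(unique(groups)), function(g)
    sort(names(groups)[groups == g])[1], character(1))
  say("three-breed designs")
  sp6 <- scenario_spec(within_breeds, design = "three_breed_group",
                       strategies = strategies, h2 = h_top,
                       n_replicates = n_replicates, seed = seeds[52])
  res[[length(res) + 1L]] <- run_grid(sp6, sim, traits)
  sp7 <- scenario_spec(cross_breeds, design = "three_breed_crossgroup",
                       strategies = strategies, h2 = h_top,
                       n_replicates = n_replicates, seed = seeds[53])
  res[[length(res) + 1L]] <- run_grid(sp7, sim, traits)

  results <- do.call(rbind, res)
  class(results) <- c("scenario_result", "data.frame")
  sm <- summary(results)

  pick <- function(design, strat = NULL, h = NULL, in_ref = TRUE) {
    d <- sm[sm$design == design & sm$in_reference == in_ref, ]
    if (!is.null(strat)) d <- d[d$strategy %in% strat, ]
    if (!is.null(h)) d <- d[d$h2 %in% h, ]
    mean(d$mean_accuracy)
  }
  headline <- list(
    within_breed_h06_strategy_I = pick("within_breed", "I", h_top),
    within_breed_h01_mean = pick("within_breed", strategies, 0.1),
    within_breed_h03_mean = pick("within_breed", strategies, 0.3),
    within_breed_h06_mean = pick("within_breed", strategies, h_top),
    across_breed_h06_mean = pick("across_breed", strategies, h_top,
                                 in_ref = FALSE),
    combined_ten_h06_strategy_I = pick("combined_ten", "I", h_top),
    three_breed_group_h06_strategy_I = pick("three_breed_group", "I", h_top),
    three_breed_crossgroup_h06_strategy_I =
      pick("three_breed_crossgroup", "I", h_top))

  list(results = results, summary = sm, headline = headline,
       groups = groups, within_group_reference = within_breeds,
       cross_group_reference = cross_breeds,
       panel_info = list(n_markers = n_markers(sim), n_ind = n_ind(sim),
                         breeds = breeds, seed = seed))
}

#' @rdname run_study
#' @export
study_founder_config <- function(seed = NULL) {
  # ~24% of generated markers drift to monomorphism across founders;
  # oversize so the surviving panel is ~20,000 SNPs at ~4 kb spacing
  founder_config(founders_per_breed = 25, n_markers = 26500L,
                 marker_spacing_bp = 3020, seed = seed)
}

#' Persistence-of-phase study: founders vs block-resampled expansion
#'
#' For each seed, generates one synthetic breed's founders, expands them
#' by block resampling, and computes the signed-LD phase correlation
#' between the founder panel and its expansion in the shortest distance
#' bin.
#'
#' @param seed master seed.
#' @param n_seeds number of independent repetitions.
#' @param founders_per_breed founders per repetition.
#' @param bins a [phase_bins()] frame; only the first (shortest) bin is
#'   summarised.
#' @param founders optional template [founder_config()]; its breed
#'   structure is collapsed to a single breed.
#' @return data frame with one row per seed: `seed`, `correlation`
#'   (shortest bin), `n_pairs`.
#' @export
phase_persistence_study <- function(seed = 1, n_seeds = 10,
                                    founders_per_breed = 25,
                                    bins = phase_bins()[1, , drop = FALSE],
                                    founders = NULL) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 2 * n_seeds)
  out <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    f <- if (is.null(founders)) study_founder_config() else founders
    f$n_breeds <- 1L
    f$groups <- 1L
    f$founders_per_breed <- founders_per_breed
    f$breed_names <- f$breed_names[1]
    f$seed <- seeds[2 * k - 1]
    cfg <- f
    fp <- generate_founders(cfg)
    sim <- expand_breed(fp, fp$breed[1],
                        resample_config(seed = seeds[2 * k]))
    pp <- phase_persistence(fp, sim, bins)
    out[[k]] <- data.frame(seed = seeds[2 * k - 1],
                           correlation = pp$correlation[1],
                           n_pairs = pp$n_pairs[1])
  }
  do.call(rbind, out)
}
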