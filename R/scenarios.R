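#' Reference/validation design specification
#'
#' Describes one reference-population design: which breeds contribute to
#' the reference, the total reference size (split equally across the
#' reference breeds), how validation sets are formed, and the trait grid
#' (strategies x heritabilities x replicates) to evaluate.
#'
#' Designs follow the three classic compositions for multi-breed genomic
#' evaluation: a single-breed reference, a three-breed reference (from
#' one cluster of related breeds, or one breed per cluster), and a pooled
#' reference combining all breeds.
#'
#' @param reference_breeds breed labels forming the reference.
#' @param design label for bookkeeping (`"single_breed"`,
#'   `"three_breed"`, `"combined"`, or free text).
#' @param n_reference total reference size (default 1200), divided
#'   equally among `reference_breeds`.
#' @param validation_per_breed held-out individuals per breed (default
#'   300). For reference breeds the validation set is drawn from the
#'   non-reference remainder; for foreign breeds it is a random draw.
#' @param foreign_validation also score breeds absent from the reference?
#' @param strategies character vector of [architecture_strategy()] preset
#'   names to evaluate.
#' @param h2 heritabilities to evaluate.
#' @param n_replicates trait replicates per grid cell.
#' @param seed seed controlling the reference/validation draw.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(reference_breeds,
                          design = if (length(reference_breeds) == 1L)
                            "single_breed" else
                              sprintf("%d_breed", length(reference_breeds)),
                          n_reference = 1200L,
                          validation_per_breed = 300L,
                          foreign_validation = FALSE,
                          strategies = c("I", "II", "III", "IV"),
                          h2 = c(0.1, 0.3, 0.6),
                          n_replicates = 10L,
                          seed = 1L) {
  n_reference <- as.integer(n_reference)
  if (n_reference %% length(reference_breeds) != 0L)
    stop("n_reference must divide equally among the reference breeds")
  if (any(h2 <= 0 | h2 >= 1)) stop("heritabilities must lie in (0, 1)")
  structure(list(design = design,
                 reference_breeds = reference_breeds,
                 n_reference = n_reference,
                 quota = n_reference %/% length(reference_breeds),
                 validation_per_breed = as.integer(validation_per_breed),
                 foreign_validation = isTRUE(foreign_validation),
                 strategies = strategies, h2 = h2,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Draw reference and validation individuals for a design
#'
#' Reference individuals are drawn without replacement, `quota` per
#' reference breed. Validation sets: for reference breeds, up to
#' `validation_per_breed` of the remaining individuals; for foreign
#' breeds (if scored), a random `validation_per_breed`. Reference and
#' validation are disjoint by construction.
#'
#' @param spec a [scenario_spec()].
#' @param panel the expanded [genotype_panel()].
#' @return list with `reference` (character ids) and `validation` (named
#'   list of id vectors, one per validation breed).
#' @export
make_splits <- function(spec, panel) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  breeds <- unique(panel$breed)
  missing_b <- setdiff(spec$reference_breeds, breeds)
  if (length(missing_b))
    stop("reference breed(s) absent from panel: ",
         paste(missing_b, collapse = ", "))
  reference <- character(0)
  validation <- list()
  for (b in spec$reference_breeds) {
    ids_b <- panel$ids[panel$breed == b]
    if (length(ids_b) < spec$quota)
      stop("breed ", b, " has fewer than the reference quota of ",
           spec$quota, " individuals")
    ref_b <- sample(ids_b, spec$quota)
    rest <- setdiff(ids_b, ref_b)
    reference <- c(reference, ref_b)
    validation[[b]] <- if (length(rest) > spec$validation_per_breed)
      sample(rest, spec$validation_per_breed) else rest
  }
  if (spec$foreign_validation) {
    for (b in setdiff(breeds, spec$reference_breeds)) {
      ids_b <- panel$ids[panel$breed == b]
      validation[[b]] <- if (length(ids_b) > spec$validation_per_breed)
        sample(ids_b, spec$validation_per_breed) else ids_b
    }
  }
  list(reference = reference, validation = validation)
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted and true breeding values.
#' Returns `NA` (recorded as missing, never zero) for fewer than 3 pairs
#' or constant input.
#'
#' @param gebv,tbv numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
accuracy <- function(gebv, tbv) {
  if (length(gebv) != length(tbv)) stop("length mismatch")
  ok <- is.finite(gebv) & is.finite(tbv)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(gebv[ok]) == 0 || stats::sd(tbv[ok]) == 0) return(NA_real_)
  stats::cor(gebv[ok], tbv[ok])
}

#' Pre-simulate a trait grid
#'
#' Draws, per (strategy, replicate), one QTL set from the pooled panel
#' (so QTL segregate in all breeds with breed-specific frequencies) and
#' the corresponding TBVs; then, per heritability, one phenotype vector.
#' Sharing a trait grid across several [run_grid()] designs evaluates all
#' designs on identical traits, mirroring a paired comparison.
#'
#' @param panel the expanded [genotype_panel()].
#' @param strategies strategy preset names.
#' @param h2 heritabilities.
#' @param n_replicates replicates per strategy.
#' @param seed master seed; per-(strategy, replicate) child seeds are
#'   spawned deterministically.
#' @param groups grouping for environmental-variance scaling (default:
#'   the panel's breed labels; see [simulate_phenotypes()]).
#' @return an object of class `trait_grid`: nested list
#'   `traits[[strategy]][[replicate]]` with elements `qtl`, `tbv`, and
#'   `phen[[as.character(h2)]]`.
#' @export
simulate_traits <- function(panel, strategies = c("I", "II", "III", "IV"),
                            h2 = c(0.1, 0.3, 0.6), n_replicates = 10L,
                            seed = 1L, groups = panel$breed) {
  set.seed(seed)
  p_all <- allele_freq(panel)
  poly <- which(p_all > 0 & p_all < 1)
  out <- list()
  for (s in strategies) {
    strat <- architecture_strategy(s)
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      qtl <- sample_qtl(panel, strat, polymorphic = poly)
      tbv <- compute_tbv(panel, qtl)
      phen <- list()
      for (h in h2)
        phen[[as.character(h)]] <- simulate_phenotypes(tbv, h, groups = groups)
      reps[[r]] <- list(qtl = qtl, tbv = tbv, phen = phen)
    }
    out[[s]] <- reps
  }
  structure(list(traits = out, strategies = strategies, h2 = h2,
                 n_replicates = n_replicates, seed = seed,
                 ids = panel$ids),
            class = "trait_grid")
}

#' Run a reference-design evaluation grid
#'
#' For one design: draws the reference/validation split, builds the GRM
#' over the analysis sample (pooled allele frequencies, markers
#' polymorphic in that sample), and for every (strategy, heritability,
#' replicate) cell fits GBLUP on the reference (fixed effects: overall
#' mean, plus breed for multi-breed references; `lambda` from the true
#' simulated heritability) and records the per-validation-breed accuracy
#' `cor(GEBV, TBV)`. The GRM and its Cholesky factor are reused across
#' replicates and strategies.
#'
#' @param spec a [scenario_spec()].
#' @param panel the expanded [genotype_panel()].
#' @param traits a [simulate_traits()] grid (created on the fly when
#'   `NULL`, using `spec`'s grid settings and `spec$seed + 1`).
#' @param ridge relative GRM ridge (see [gblup()]).
#' @return an object of class `scenario_result`: data frame with columns
#'   `design`, `reference`, `strategy`, `h2`, `replicate`, `val_breed`,
#'   `in_reference`, `n_val`, `accuracy`.
#' @export
run_grid <- function(spec, panel, traits = NULL, ridge = 1e-6) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(traits))
    traits <- simulate_traits(panel, spec$strategies, spec$h2,
                              spec$n_replicates, seed = spec$seed + 1L)
  splits <- make_splits(spec, panel)
  val_ids <- unlist(splits$validation, use.names = FALSE)
  analysis_ids <- c(splits$reference, val_ids)

  # markers polymorphic in the analysis sample
  p <- allele_freq(panel, individuals = analysis_ids)
  poly <- which(p > 0 & p < 1)
  grm <- compute_grm(panel, individuals = analysis_ids, markers = poly)

  rid <- match(splits$reference, grm$ids)
  ref_breed <- panel$breed[match(splits$reference, panel$ids)]
  multi <- length(spec$reference_breeds) > 1L
  X <- if (multi) stats::model.matrix(~breed, data.frame(breed = factor(ref_breed)))
       else matrix(1, length(rid), 1, dimnames = list(NULL, "(Intercept)"))

  vb_ids <- splits$validation
  vb_rows <- lapply(vb_ids, function(ids) match(ids, grm$ids))
  panel_pos <- match(grm$ids[rid], traits$ids)
  vb_pos <- lapply(vb_ids, function(ids) match(ids, traits$ids))

  Grr <- grm$G[rid, rid, drop = FALSE]
  eps <- ridge * mean(diag(Grr))
  records <- list()
  for (h in spec$h2) {
    lambda <- (1 - h) / h
    M <- Grr
    diag(M) <- diag(M) + eps + lambda
    ch <- chol(M)
    for (s in spec$strategies) {
      for (r in seq_len(spec$n_replicates)) {
        tr <- traits$traits[[s]][[r]]
        y <- tr$phen[[as.character(h)]]$y[panel_pos]
        sol <- gblup_core(grm, rid, integer(0), X, y, lambda, ridge,
                          chol_cache = ch)
        for (b in names(vb_ids)) {
          gv <- drop(grm$G[vb_rows[[b]], rid, drop = FALSE] %*% sol$alpha)
          records[[length(records) + 1L]] <- data.frame(
            design = spec$design,
            reference = paste(spec$reference_breeds, collapse = "+"),
            strategy = s, h2 = h, replicate = r, val_breed = b,
            in_reference = b %in% spec$reference_breeds,
            n_val = length(vb_ids[[b]]),
            accuracy = accuracy(gv, tr$tbv[vb_pos[[b]]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, records)
  class(out) <- c("scenario_result", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Summarise scenario accuracies
#'
#' Mean and standard deviation of accuracy per (design, strategy, h2,
#' in/out of reference), averaging first over validation breeds within a
#' replicate, then over replicates (the conventional reporting order for
#' multi-breed evaluations).
#'
#' @param object a [run_grid()] result (or several `rbind`ed together).
#' @param ... unused.
#' @return data frame of summary rows.
#' @export
summary.scenario_result <- function(object, ...) {
  df <- as.data.frame(object)
  key <- interaction(df$design, df$reference, df$strategy, df$h2,
                     df$in_reference, drop = TRUE)
  rows <- lapply(split(df, key), function(d) {
    per_rep <- tapply(d$accuracy, d$replicate, mean, na.rm = TRUE)
    data.frame(design = d$design[1], reference = d$reference[1],
               strategy = d$strategy[1], h2 = d$h2[1],
               in_reference = d$in_reference[1],
               n_breeds = length(unique(d$val_breed)),
               mean_accuracy = mean(per_rep), sd_accuracy = stats::sd(per_rep),
               n_replicates = length(per_rep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$design, out$reference, out$h2, out$strategy), ]
}
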