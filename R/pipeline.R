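# Leave-one-out experiment orchestration: pooling, the LOO loop, the
# phenotype-permutation null and the random genic/non-genic floor analysis.

#' Pool studies into one training panel
#'
#' Stacks genotype, phenotype and covariate matrices of several studies that
#' share a SNP panel, and appends 0/1 study-indicator columns (first study as
#' reference) so pooled regressions adjust for cohort membership.
#'
#' @param studies named list of `genotype_study` objects.
#' @param exclude study names to leave out (e.g. the held-out cohort).
#' @return object of class `study_pool`: `y`, `geno`, `covariates`, `snps`,
#'   `study_of` (factor), `study_ids`.
#' @export
pool_studies <- function(studies, exclude = NULL) {
  use <- setdiff(names(studies), exclude)
  if (length(use) == 0)
    omniprs_error("no studies left after exclusion", "omniprs_error_empty")
  ref <- studies[[use[1]]]$snps$snp_id
  for (s in use)
    if (!identical(studies[[s]]$snps$snp_id, ref))
      omniprs_error("studies do not share a SNP panel", "omniprs_error_alignment")
  geno <- do.call(rbind, lapply(studies[use], `[[`, "geno"))
  y <- unlist(lapply(studies[use], `[[`, "phenotype"), use.names = FALSE)
  covs <- do.call(rbind, lapply(studies[use], `[[`, "covariates"))
  study_of <- factor(rep(use, vapply(studies[use], function(s) nrow(s$geno), 0L)),
                     levels = use)
  if (length(use) > 1) {
    ind <- sapply(use[-1], function(s) as.numeric(study_of == s))
    colnames(ind) <- paste0("study_", use[-1])
    covs <- if (is.null(covs)) ind else cbind(covs, ind)
  }
  structure(list(y = y, geno = geno, covariates = covs,
                 snps = studies[[use[1]]]$snps, study_of = study_of,
                 study_ids = use),
            class = "study_pool")
}

# Training-side computation for every LOO iteration: pooled GWAS, risk
# orientation and LD pruning on all-but-one studies. The held-out study is
# excluded before anything is computed, so no training quantity can depend
# on it. `prune_cache` (named by held-out study) substitutes precomputed
# prune lists; pruning depends only on genotypes, so the cache is exact.
loo_training <- function(studies, prune = prune_params(), prune_cache = NULL) {
  out <- lapply(names(studies), function(s) {
    pool <- pool_studies(studies, exclude = s)
    stats <- orient_risk(gwas(pool))
    pruned <- if (is.null(prune)) pool$snps$snp_id
              else prune_cache[[s]] %||% ld_prune(pool$geno, prune)
    list(held_out = s, pool = pool, stats = stats, pruned = pruned)
  })
  names(out) <- names(studies)
  out
}

# Evaluate one SNP set on one held-out study given its training context.
loo_eval_one <- function(train, study, snp_set, grid) {
  eligible <- intersect(snp_set, train$pruned)
  rec <- data.frame(held_out_study = train$held_out, selected_cutoff = NA_real_,
                    n_snps = length(eligible), lrt_stat = NA_real_,
                    p_value = NA_real_, nested_r2 = NA_real_,
                    direction = NA_real_,
                    n_cases = sum(study$phenotype == 1L, na.rm = TRUE),
                    n_controls = sum(study$phenotype == 0L, na.rm = TRUE),
                    flagged = TRUE, stringsAsFactors = FALSE)
  if (length(eligible) == 0) return(rec)
  sel <- tryCatch(select_threshold(train$pool, train$stats, eligible, grid),
                  omniprs_error = function(e) NULL)
  if (is.null(sel)) return(rec)
  rec$selected_cutoff <- sel$best_cutoff
  sv <- withCallingHandlers(
    prs_score(study, train$stats, eligible, sel$best_cutoff),
    omniprs_warning = function(w) invokeRestart("muffleWarning"))
  y <- study$phenotype
  if (sv$n_snps == 0L || var(sv$score) == 0) return(rec)
  Xb <- cbind(study$covariates, valid_ct = sv$valid_count)
  Xf <- cbind(Xb, score = sv$score)
  fits <- tryCatch(suppressWarnings(list(
    null = fit_logistic(y, NULL),
    base = fit_logistic(y, Xb),
    full = fit_logistic(y, Xf))), error = function(e) NULL)
  if (is.null(fits) || fits$full$df <= fits$base$df) return(rec)
  test <- tryCatch(lrt(fits$full, fits$base, df = 1),
                   omniprs_error = function(e) NULL)
  if (is.null(test)) return(rec)
  n <- fits$full$n
  r2_full <- nagelkerke(fits$full$loglik, fits$null$loglik, n)
  r2_base <- nagelkerke(fits$base$loglik, fits$null$loglik, n)
  rec$lrt_stat <- test$statistic
  rec$p_value <- test$p_value
  rec$nested_r2 <- max(0, r2_full - r2_base)
  beta_score <- fits$full$coefficients[["score"]]
  rec$direction <- if (beta_score >= 0) 1 else -1
  rec$flagged <- fits$full$flagged || fits$base$flagged
  rec
}

#' Leave-one-out PRS analysis over one or more SNP sets
#'
#' For each study in turn: a pooled training GWAS on all other studies, risk
#' orientation, LD pruning, restriction to the SNP set, in-training p-value
#' threshold selection, scoring of the held-out study and a nested
#' covariate-adjusted logistic evaluation (LRT p, nested Nagelkerke R^2,
#' effect direction). Held-out records are then meta-analyzed with
#' [stouffer()]. Training GWAS and pruning do not depend on the SNP set and
#' are shared across sets.
#'
#' @param studies named list of >= 3 `genotype_study` objects sharing a panel.
#' @param snp_sets named list of character SNP-id vectors.
#' @param grid a [threshold_grid()].
#' @param prune a [prune_params()], or `NULL` to skip pruning (genome-wide
#'   mode).
#' @param weight Stouffer weighting, see [stouffer()].
#' @param prune_cache optional named list of precomputed per-iteration prune
#'   results (exact, since pruning only reads genotypes).
#' @param training optional precomputed [loo_training] result.
#' @param keep_training return the training contexts (for leak audits).
#' @return for `loo_run_multi`: named list per set, each with `records` (one
#'   row per held-out study) and `meta` (a `meta_result`); attribute
#'   `training` when requested. `loo_run` takes a single `snp_set` and
#'   returns one such element.
#' @export
loo_run_multi <- function(studies, snp_sets, grid = threshold_grid(),
                          prune = prune_params(), weight = "total",
                          prune_cache = NULL, training = NULL,
                          keep_training = FALSE) {
  if (length(studies) < 3)
    omniprs_error("need at least 3 studies for leave-one-out",
                  "omniprs_error_config")
  if (is.null(training))
    training <- loo_training(studies, prune = prune, prune_cache = prune_cache)
  out <- lapply(snp_sets, function(snp_set) {
    records <- do.call(rbind, lapply(training, function(tr)
      loo_eval_one(tr, studies[[tr$held_out]], snp_set, grid)))
    rownames(records) <- NULL
    meta <- tryCatch(stouffer(records, weight = weight),
                     omniprs_error = function(e) NULL)
    list(records = records, meta = meta)
  })
  names(out) <- names(snp_sets)
  if (keep_training) attr(out, "training") <- training
  out
}

#' @rdname loo_run_multi
#' @param snp_set a single character vector of SNP ids.
#' @export
loo_run <- function(studies, snp_set, grid = threshold_grid(),
                    prune = prune_params(), weight = "total",
                    prune_cache = NULL, training = NULL,
                    keep_training = FALSE) {
  res <- loo_run_multi(studies, list(set = snp_set), grid = grid,
                       prune = prune, weight = weight,
                       prune_cache = prune_cache, training = training,
                       keep_training = keep_training)
  out <- res$set
  if (keep_training) attr(out, "training") <- attr(res, "training")
  out
}

#' Permute phenotypes within each study
#'
#' Case/control labels are shuffled among each study's samples, preserving
#' per-study margins (and thereby any study-indicator structure).
#'
#' @param studies named list of `genotype_study` objects.
#' @param seed permutation seed.
#' @return the studies with permuted phenotypes.
#' @export
permute_phenotypes <- function(studies, seed) {
  with_seed(as.integer(seed), {
    lapply(studies, function(st) {
      st$phenotype <- sample(st$phenotype)
      st
    })
  })
}

#' Experiment-wise phenotype-permutation null
#'
#' Permutes phenotypes within study `n_permutations` times and re-runs the
#' entire leave-one-out pipeline (training GWAS included) on each permuted
#' panel, recording whether the meta-analytic p-value falls below `alpha`.
#' With a calibrated pipeline the rejection fraction should be ~`alpha`.
#' LD pruning reads only genotypes, which permutation leaves untouched, so
#' the per-iteration prune results are computed once and reused.
#'
#' @param studies named list of `genotype_study` objects.
#' @param snp_set SNP ids of the tested set.
#' @param n_permutations number of phenotype permutations.
#' @param alpha experiment-wise significance level.
#' @param seed root seed for the permutation streams.
#' @inheritParams loo_run_multi
#' @return list: `rejection_fraction`, `n_reject`, `n_permutations`,
#'   `ci` (exact binomial 95% CI), `p_meta` (per-permutation meta p-values).
#' @export
permutation_experiment <- function(studies, snp_set, n_permutations = 100L,
                                   alpha = 0.05, seed = 1L,
                                   grid = threshold_grid(),
                                   prune = prune_params(), weight = "total") {
  stopifnot(n_permutations >= 1)
  prune_cache <- if (is.null(prune)) NULL else loo_training_prunes(studies, prune)
  p_meta <- vapply(seq_len(n_permutations), function(b) {
    perm <- permute_phenotypes(studies, derive_seed(seed, "perm", b))
    res <- loo_run(perm, snp_set, grid = grid, prune = prune,
                   weight = weight, prune_cache = prune_cache)
    if (is.null(res$meta)) NA_real_ else res$meta$p_meta
  }, numeric(1))
  n_reject <- sum(p_meta < alpha, na.rm = TRUE)
  ci <- as.numeric(binom.test(n_reject, n_permutations)$conf.int)
  list(rejection_fraction = n_reject / n_permutations, n_reject = n_reject,
       n_permutations = n_permutations, ci = ci, p_meta = p_meta)
}

# Prune lists per held-out study (genotype-only; shared across permutations).
loo_training_prunes <- function(studies, prune) {
  out <- lapply(names(studies), function(s) {
    pool <- pool_studies(studies, exclude = s)
    ld_prune(pool$geno, prune)
  })
  names(out) <- names(studies)
  out
}

#' Random genic / non-genic floor analysis
#'
#' Estimates the "omnigenic floor": the meta-analytic significance and nested
#' R^2 that random SNP sets achieve. SNPs are classified genic/non-genic,
#' each pool is LD-pruned at a strict threshold (r^2 < 0.01 by default) so
#' only quasi-independent SNPs are sampled, random sets are drawn from each
#' pool, and the full leave-one-out pipeline is run for every set.
#'
#' @param studies named list of `genotype_study` objects.
#' @param classification a [classify_genic()] result for the panel.
#' @param n_sets,set_size random sets per pool and SNPs per set.
#' @param pool_prune [prune_params()] for the pool pruning step.
#' @param seed seed for the random draws.
#' @inheritParams loo_run_multi
#' @return list with elements `genic` and `nongenic`, each holding `sets`
#'   (per-set meta results), `records`, `p_median`, `p_range`, `r2_median`,
#'   `r2_range`; plus `pool_sizes`.
#' @export
floor_analysis <- function(studies, classification, n_sets = 50L,
                           set_size = 5000L,
                           pool_prune = prune_params(r2_max = 0.01),
                           seed = 1L, grid = threshold_grid(),
                           prune = prune_params(), weight = "total") {
  pool_all <- pool_studies(studies)
  pruned_pool <- ld_prune(pool_all$geno, pool_prune)
  genic_ids <- names(classification$genic)[classification$genic]
  pools <- list(genic = intersect(pruned_pool, genic_ids),
                nongenic = setdiff(pruned_pool, genic_ids))
  sets <- c(draw_random_sets(pools$genic, n_sets, set_size,
                             seed = derive_seed(seed, "floor_genic"),
                             prefix = "genic"),
            draw_random_sets(pools$nongenic, n_sets, set_size,
                             seed = derive_seed(seed, "floor_nongenic"),
                             prefix = "nongenic"))
  res <- loo_run_multi(studies, sets, grid = grid, prune = prune,
                       weight = weight)
  summarize_pool <- function(prefix) {
    rs <- res[startsWith(names(res), prefix)]
    metas <- Filter(Negate(is.null), lapply(rs, `[[`, "meta"))
    p <- vapply(metas, `[[`, 0, "p_meta")
    r2 <- vapply(metas, `[[`, 0, "r2_median")
    list(sets = metas,
         records = do.call(rbind, lapply(names(rs), function(nm)
           cbind(set = nm, rs[[nm]]$records))),
         p_median = median(p), p_range = range(p),
         r2_median = median(r2), r2_range = range(r2))
  }
  list(genic = summarize_pool("genic"),
       nongenic = summarize_pool("nongenic"),
       pool_sizes = lengths(pools))
}
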