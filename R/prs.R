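# Polygenic score computation over SNP sets at a p-value cutoff grid, and
# in-training threshold selection.

#' The p-value cutoff grid
#'
#' Nine cutoffs used to build candidate scores; the single score tested on a
#' held-out study is selected on the training data only.
#'
#' @param p_cutoffs strictly increasing cutoffs in (0, 1].
#' @return numeric vector of class `threshold_grid`.
#' @export
threshold_grid <- function(p_cutoffs = c(0.0001, 0.001, 0.01, 0.05, 0.10,
                                         0.20, 0.30, 0.40, 0.50)) {
  if (any(diff(p_cutoffs) <= 0) || any(p_cutoffs <= 0) || any(p_cutoffs > 1))
    omniprs_error("cutoffs must be strictly increasing and in (0, 1]",
                  "omniprs_error_config")
  structure(p_cutoffs, class = "threshold_grid")
}

#' Compute a polygenic score
#'
#' Sum score over the SNPs of `snp_set` whose training p-value is strictly
#' below `p_cutoff`: `score_i = sum_j lnOR_j * (risk-allele dosage)_ij`.
#' Dosages are re-oriented to the risk allele of the (oriented) summary
#' statistics; a missing genotype contributes 0 to the score and decrements
#' the per-sample valid-genotype count.
#'
#' @param panel a `genotype_study` or `study_pool` (anything with `geno` and
#'   `snps` fields).
#' @param stats oriented summary statistics (all `lnor >= 0`, see
#'   [orient_risk()]).
#' @param snp_set character vector of SNP ids to score over.
#' @param p_cutoff training p-value cutoff (strict inequality).
#' @return list of class `score_vector`: `score`, `valid_count` (per sample),
#'   `n_snps` (size of the scored set).
#' @export
prs_score <- function(panel, stats, snp_set, p_cutoff) {
  if (any(stats$lnor < 0))
    omniprs_error("summary statistics must be risk-oriented (lnor >= 0)",
                  "omniprs_error_orientation")
  sel <- stats[stats$snp_id %in% snp_set & stats$p < p_cutoff, , drop = FALSE]
  n <- nrow(panel$geno)
  if (nrow(sel) == 0) {
    omniprs_warn(sprintf("no SNPs pass p < %g in this set: all-zero score", p_cutoff),
                 "omniprs_warning_empty_score")
    return(structure(list(score = rep(0, n), valid_count = rep(0L, n),
                          n_snps = 0L), class = "score_vector"))
  }
  idx <- match(sel$snp_id, panel$snps$snp_id)
  if (anyNA(idx))
    omniprs_error("scored SNP(s) absent from panel", "omniprs_error_alignment")
  G <- panel$geno[, idx, drop = FALSE]
  flip <- sel$a1 != panel$snps$a1[idx]
  if (any(flip)) G[, flip] <- 2 - G[, flip]
  miss <- is.na(G)
  G[miss] <- 0
  structure(list(score = as.numeric(G %*% sel$lnor),
                 valid_count = as.integer(nrow(sel) - rowSums(miss)),
                 n_snps = nrow(sel)),
            class = "score_vector")
}

#' Select the p-value threshold on the training data
#'
#' For every cutoff of the grid, fits covariates + valid-genotype count +
#' score against covariates + valid-genotype count on the training samples
#' and records the likelihood-ratio chi-square of the score term. The
#' selected cutoff maximizes that statistic; ties go to the smallest cutoff,
#' so exactly one score is ever carried to the held-out study.
#'
#' @param pool training `study_pool`.
#' @param stats oriented training summary statistics.
#' @param snp_set SNP ids defining the set.
#' @param grid a [threshold_grid()].
#' @return list: `best_cutoff`, `best_statistic` and `table` (one row per
#'   cutoff: `cutoff`, `n_snps`, `statistic`, `p_value`, `degenerate`).
#' @export
select_threshold <- function(pool, stats, snp_set, grid = threshold_grid()) {
  y <- pool$y
  rows <- lapply(as.numeric(grid), function(cut) {
    sv <- withCallingHandlers(
      prs_score(pool, stats, snp_set, cut),
      omniprs_warning = function(w) invokeRestart("muffleWarning"))
    if (sv$n_snps == 0L || var(sv$score) == 0)
      return(data.frame(cutoff = cut, n_snps = sv$n_snps, statistic = 0,
                        p_value = 1, degenerate = TRUE))
    Xb <- cbind(pool$covariates, valid_ct = sv$valid_count)
    Xf <- cbind(Xb, score = sv$score)
    suppressWarnings({
      base <- fit_logistic(y, Xb)
      full <- fit_logistic(y, Xf)
    })
    if (full$df <= base$df)  # score column collapsed into covariates
      return(data.frame(cutoff = cut, n_snps = sv$n_snps, statistic = 0,
                        p_value = 1, degenerate = TRUE))
    test <- lrt(full, base, df = 1)
    data.frame(cutoff = cut, n_snps = sv$n_snps, statistic = test$statistic,
               p_value = test$p_value, degenerate = full$flagged || base$flagged)
  })
  tab <- do.call(rbind, rows)
  if (all(tab$degenerate))
    omniprs_error("all cutoffs degenerate for this SNP set",
                  "omniprs_error_degenerate")
  usable <- tab[!tab$degenerate, , drop = FALSE]
  best <- usable[which.max(usable$statistic), ]  # which.max: first max = smallest cutoff
  list(best_cutoff = best$cutoff, best_statistic = best$statistic, table = tab)
}
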