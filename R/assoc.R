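# Logistic-model machinery: covariate-adjusted logistic fits, the per-SNP
# training GWAS, risk-allele orientation, likelihood-ratio tests and
# Nagelkerke's pseudo R-squared.

#' Fit a logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome on a predictor matrix
#' (intercept added automatically). Rank-deficient columns are dropped with a
#' warning; (quasi-)perfect separation yields a flagged result with capped
#' coefficients rather than an error.
#'
#' @param y binary response (0/1); `NA`s are dropped together with the
#'   matching rows of `X`.
#' @param X numeric predictor matrix or `NULL` for the intercept-only model.
#' @return object of class `fit_result`: `coefficients`, `loglik`, `n`,
#'   `df` (number of estimated parameters), `converged`, `flagged`.
#' @export
fit_logistic <- function(y, X = NULL) {
  if (!is.null(X)) X <- as.matrix(X)
  keep <- !is.na(y)
  if (!is.null(X)) keep <- keep & stats::complete.cases(X)
  y <- y[keep]
  n <- length(y)
  if (n == 0) omniprs_error("no usable samples", "omniprs_error_empty")
  Xf <- cbind(`(Intercept)` = rep(1, n),
              if (!is.null(X)) X[keep, , drop = FALSE])
  if (is.null(colnames(Xf)))
    colnames(Xf) <- c("(Intercept)", sprintf("V%d", seq_len(ncol(Xf) - 1)))
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qrX$pivot[-seq_len(qrX$rank)]]
    omniprs_warn(sprintf("dropping rank-deficient column(s): %s",
                         paste(dropped, collapse = ", ")),
                 "omniprs_warning_rank_deficient")
    Xf <- Xf[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  fit <- suppressWarnings(glm.fit(Xf, y, family = stats::binomial()))
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  beta <- fit$coefficients
  # separation heuristic on the standardized scale (|beta_j| * sd(x_j)), so
  # uncentered predictors with large offsets are not falsely flagged
  sds <- apply(Xf[, -1, drop = FALSE], 2, sd)
  big <- ncol(Xf) > 1 & abs(beta[-1]) * sds > 15
  flagged <- !fit$converged || any(big, na.rm = TRUE)
  if (flagged) {
    omniprs_warn("possible separation: coefficients capped, fit flagged",
                 "omniprs_warning_separation")
    if (any(big, na.rm = TRUE)) {
      cap <- 15 / sds[big]
      beta[-1][big] <- sign(beta[-1][big]) * cap
    }
  }
  structure(list(coefficients = beta, loglik = ll, n = n,
                 df = ncol(Xf), converged = fit$converged, flagged = flagged),
            class = "fit_result")
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,base `fit_result` objects, `base` nested in `full`.
#' @param df degrees of freedom; defaults to the parameter-count difference.
#' @return list `statistic` (chi-square, clipped at 0) and `p_value`.
#' @export
lrt <- function(full, base, df = full$df - base$df) {
  if (df <= 0)
    omniprs_error("invalid nesting: df must be positive", "omniprs_error_nesting")
  stat <- 2 * (full$loglik - base$loglik)
  if (stat < -1e-6 * max(1, abs(base$loglik)))
    omniprs_error("full-model log-likelihood below base model: convergence failure",
                  "omniprs_error_convergence")
  stat <- max(stat, 0)
  list(statistic = stat, p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Nagelkerke pseudo R-squared
#'
#' `R2 = (1 - exp((2/n) (ll_null - ll_model))) / (1 - exp((2/n) ll_null))`,
#' with `ll_null` the intercept-only log-likelihood on the same samples.
#'
#' @param ll_model,ll_null log-likelihoods.
#' @param n sample count.
#' @return R-squared in `[0, 1]`.
#' @export
nagelkerke <- function(ll_model, ll_null, n) {
  if (n == 0) omniprs_error("n must be positive", "omniprs_error_empty")
  denom <- 1 - exp((2 / n) * ll_null)
  if (denom == 0) return(0)
  (1 - exp((2 / n) * (ll_null - ll_model))) / denom
}

#' Per-SNP logistic training GWAS
#'
#' Fits phenotype ~ dosage + covariates for every SNP of a pooled training
#' panel (study-indicator covariates included by the pooling step) and
#' returns per-SNP ln(odds ratio), standard error and two-sided Wald p-value
#' with the .bim A1 allele as the effect allele. Samples with a missing
#' dosage at a SNP are dropped for that SNP only. Monomorphic SNPs get
#' `lnor = 0, p = 1` and are flagged.
#'
#' @param pool a `study_pool` (see [pool_studies()]).
#' @return summary-statistics data.frame: `snp_id`, `a1`, `a2`, `lnor`, `se`,
#'   `p`, `n`, `flagged`.
#' @export
gwas <- function(pool) {
  stopifnot(inherits(pool, "study_pool"))
  keep <- !is.na(pool$y)
  y <- as.numeric(pool$y[keep])
  C <- cbind(1, pool$covariates[keep, , drop = FALSE])
  G <- pool$geno[keep, , drop = FALSE]
  base <- suppressWarnings(glm.fit(C, y, family = stats::binomial()))
  res <- logistic_gwas_cpp(y, C, G, base$coefficients)
  z <- res[, "beta"] / res[, "se"]
  p <- 2 * pnorm(-abs(z))
  mono <- res[, "monomorphic"] == 1
  bad <- mono | res[, "converged"] == 0 | !is.finite(p) |
    abs(res[, "beta"]) > 15
  lnor <- res[, "beta"]
  lnor[mono] <- 0
  p[mono | !is.finite(p)] <- 1
  data.frame(snp_id = pool$snps$snp_id, a1 = pool$snps$a1, a2 = pool$snps$a2,
             lnor = lnor, se = res[, "se"], p = p,
             n = as.integer(res[, "n_used"]), flagged = bad,
             stringsAsFactors = FALSE)
}

#' Orient all summary statistics to the risk allele
#'
#' SNPs with negative ln(OR) have their effect and other alleles swapped and
#' the ln(OR) negated, so every SNP is coded for the allele with OR > 1.
#' ln(OR) exactly 0 is left unchanged (A1 kept). Idempotent.
#'
#' @param stats summary-statistics data.frame from [gwas()].
#' @return the oriented data.frame; all `lnor >= 0`.
#' @export
orient_risk <- function(stats) {
  flip <- stats$lnor < 0
  a1 <- stats$a1
  stats$a1[flip] <- stats$a2[flip]
  stats$a2[flip] <- a1[flip]
  stats$lnor[flip] <- -stats$lnor[flip]
  stats
}
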