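# Stouffer's Z meta-analysis across held-out studies, R^2 summaries,
# decile binning of training p-values, and the expected-floor allocation.

#' Stouffer's weighted Z meta-analysis of held-out results
#'
#' Each held-out record contributes a signed z-score
#' `z_i = sign_i * qnorm(1 - p_i / 2)` (two-sided p plus the direction of the
#' held-out PRS coefficient). The combined statistic is
#' `z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))` with sample-size weights
#' `w_i = sqrt(n_i)`; the meta p-value is two-sided. Flagged (degenerate)
#' records are excluded with a logged count.
#'
#' @param records data.frame of leave-one-out records with columns `p_value`,
#'   `direction` (+1/-1), `n_cases`, `n_controls` and optionally `flagged`,
#'   `nested_r2` (see [loo_run()]).
#' @param weight `"total"` uses `n = cases + controls`; `"effective"` uses
#'   `4 / (1/cases + 1/controls)`.
#' @param alpha per-study significance level for the `k_significant` count.
#' @return list of class `meta_result`: `z_meta`, `p_meta`, `k_significant`,
#'   `n_studies`, `n_excluded`, and the [summarize_r2()] fields when
#'   `nested_r2` is present.
#' @export
stouffer <- function(records, weight = c("total", "effective"), alpha = 0.05) {
  weight <- match.arg(weight)
  if (nrow(records) == 0)
    omniprs_error("no records to meta-analyze", "omniprs_error_empty")
  flagged <- if ("flagged" %in% names(records)) records$flagged else FALSE
  n_excluded <- sum(flagged)
  rec <- records[!flagged, , drop = FALSE]
  if (nrow(rec) == 0)
    omniprs_error("all records flagged; nothing to meta-analyze",
                  "omniprs_error_empty")
  p <- rec$p_value
  if (any(p <= 0)) {
    omniprs_warn("p-value(s) of 0 clamped to the smallest representable positive",
                 "omniprs_warning_p_clamp")
    p[p <= 0] <- .Machine$double.xmin
  }
  n <- if (weight == "total") rec$n_cases + rec$n_controls
       else 4 / (1 / rec$n_cases + 1 / rec$n_controls)
  z <- rec$direction * qnorm(1 - p / 2)
  w <- sqrt(n)
  z_meta <- sum(w * z) / sqrt(sum(w^2))
  res <- list(z_meta = z_meta, p_meta = 2 * pnorm(-abs(z_meta)),
              k_significant = sum(rec$p_value < alpha),
              n_studies = nrow(rec), n_excluded = n_excluded)
  if ("nested_r2" %in% names(rec)) res <- c(res, summarize_r2(rec))
  structure(res, class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result: z = %.3f, p = %.3g, %d/%d held-out sets p < 0.05%s>\n",
              x$z_meta, x$p_meta, x$k_significant, x$n_studies,
              if (!is.null(x$r2_median))
                sprintf(", median nested R2 = %.4g", x$r2_median) else ""))
  invisible(x)
}

#' Summaries of nested R-squared across held-out studies
#'
#' Median, interquartile range and range, using the linear-interpolation
#' quantile convention (R's default, type 7).
#'
#' @param records data.frame with a `nested_r2` column (>= 1 row).
#' @return list `r2_median`, `r2_iqr`, `r2_range` (length-2 vector).
#' @export
summarize_r2 <- function(records) {
  stopifnot(nrow(records) >= 1)
  v <- records$nested_r2
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  list(r2_median = median(v), r2_iqr = q[2] - q[1], r2_range = range(v))
}

#' Decile binning of training p-values over a SNP set
#'
#' Under the null, GWAS p-values are uniform on (0, 1), so each decile bin
#' holds 10% of SNPs; an excess in the first bin indicates enrichment.
#' Bins are `[0, 0.1), ..., [0.9, 1]`.
#'
#' @param stats summary statistics ([gwas()] output).
#' @param snp_set SNP ids to restrict to (default: all).
#' @return numeric vector of 10 proportions summing to 1.
#' @export
decile_bins <- function(stats, snp_set = stats$snp_id) {
  p <- stats$p[stats$snp_id %in% snp_set]
  if (length(p) == 0)
    omniprs_error("empty SNP set", "omniprs_error_empty")
  bin <- pmin(floor(p * 10), 9)
  as.numeric(table(factor(bin, levels = 0:9))) / length(p)
}

#' Expected variance share of a SNP set under equal per-SNP contribution
#'
#' If every SNP contributed equally to a genome-wide score explaining
#' `r2_genomewide`, a set of `n_snps_set` of the `n_snps_genomewide` SNPs
#' would explain `r2_genomewide * n_snps_set / n_snps_genomewide` — the
#' "omnigenic floor" a gene set must beat to claim a specific contribution.
#'
#' @param r2_genomewide genome-wide nested R-squared.
#' @param n_snps_genomewide,n_snps_set SNP counts.
#' @return the expected proportion (same scale as `r2_genomewide`).
#' @export
expected_share <- function(r2_genomewide, n_snps_genomewide, n_snps_set) {
  if (n_snps_genomewide <= 0)
    omniprs_error("n_snps_genomewide must be positive", "omniprs_error_config")
  r2_genomewide * n_snps_set / n_snps_genomewide
}
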