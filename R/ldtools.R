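# Pairwise LD (r^2 of additive dosages) and sliding-window LD pruning.

#' Pruning parameters
#'
#' Defaults are the conventional indep-pairwise settings for PRS discovery
#' panels: a sliding window of 50 SNPs advancing by 5, removing SNPs until no
#' retained pair within a window has r^2 above 0.25. Random-set pools use the
#' stricter `r2_max = 0.01`.
#'
#' @param window_snps window width in SNPs.
#' @param step_snps window step in SNPs (<= `window_snps`).
#' @param r2_max maximum retained pairwise r^2, in (0, 1).
#' @return list of class `prune_params`.
#' @export
prune_params <- function(window_snps = 50L, step_snps = 5L, r2_max = 0.25) {
  stopifnot(step_snps >= 1, step_snps <= window_snps,
            r2_max > 0, r2_max < 1)
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps), r2_max = r2_max),
            class = "prune_params")
}

#' Squared dosage correlation between two SNPs
#'
#' Squared Pearson correlation of additive dosages over pairwise-complete
#' samples. A monomorphic SNP cannot be in LD: zero variance at either SNP
#' yields `r2 = 0` with a warning.
#'
#' @param a,b dosage vectors (0/1/2, `NA` allowed).
#' @return r^2 in `[0, 1]`.
#' @export
snp_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2)
    omniprs_error("need >= 2 pairwise-complete samples", "omniprs_error_empty")
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0) {
    omniprs_warn("monomorphic SNP: r2 defined as 0", "omniprs_warning_monomorphic")
    return(0)
  }
  cor(a, b)^2
}

#' Sliding-window LD pruning
#'
#' Slides a window of `window_snps` SNPs over the panel (in genomic order),
#' advancing `step_snps` at a time. Within each window, while any retained
#' pair has r^2 above `r2_max`, the later-positioned SNP of the
#' first offending pair (scanning pairs in genomic order) is removed.
#' Output preserves genomic order; after completion no retained pair within
#' any window position exceeds `r2_max`.
#'
#' @param geno dosage matrix (samples x SNPs), columns in (chrom, pos) order,
#'   column names = SNP ids. Missing dosages are handled by pairwise-complete
#'   correlation; monomorphic columns are treated as r^2 = 0 against
#'   everything.
#' @param params a [prune_params()].
#' @return character vector of retained SNP ids, in panel order.
#' @export
ld_prune <- function(geno, params = prune_params()) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  ids <- colnames(geno)
  if (is.null(ids)) ids <- sprintf("snp%d", seq_len(ncol(geno)))
  kept <- ld_prune_cpp(geno, params$window_snps, params$step_snps,
                       params$r2_max)
  ids[kept]
}
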