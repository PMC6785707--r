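# PLINK-style text I/O (.bim/.fam/.traw), BED6, GMT, summary-statistics TSV,
# and the genotype QC filter chain.
#
# Internal coordinates are 1-based inclusive; BED is read and written as
# 0-based half-open. The .traw dosage dialect counts copies of the .bim A1
# allele, one row per SNP, one column per sample, missing = NA.

#' Write a study as PLINK-style text files
#'
#' @param study a `genotype_study`.
#' @param prefix path prefix; writes `<prefix>.bim`, `<prefix>.fam`,
#'   `<prefix>.traw` and, when covariates are present, `<prefix>.covar`.
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, prefix) {
  bim <- data.frame(chrom = study$snps$chrom, snp_id = study$snps$snp_id,
                    cm = 0, pos = study$snps$pos,
                    a1 = study$snps$a1, a2 = study$snps$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  pheno_code <- ifelse(is.na(study$phenotype), 0L, study$phenotype + 1L)
  fam <- data.frame(fid = study$study_id, iid = study$sample_ids,
                    pat = 0L, mat = 0L, sex = 0L, phe = pheno_code)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  traw <- data.frame(CHR = study$snps$chrom, SNP = study$snps$snp_id,
                     `(C)M` = 0, POS = study$snps$pos,
                     COUNTED = study$snps$a1, ALT = study$snps$a2,
                     check.names = FALSE)
  dos <- as.data.frame(t(study$geno))
  names(dos) <- paste(study$study_id, study$sample_ids, sep = "_")
  data.table::fwrite(cbind(traw, dos), paste0(prefix, ".traw"),
                     sep = "\t", na = "NA", quote = FALSE)
  files <- paste0(prefix, c(".bim", ".fam", ".traw"))
  if (!is.null(study$covariates)) {
    cv <- data.frame(FID = study$study_id, IID = study$sample_ids,
                     study$covariates, check.names = FALSE)
    data.table::fwrite(cv, paste0(prefix, ".covar"), sep = "\t")
    files <- c(files, paste0(prefix, ".covar"))
  }
  invisible(files)
}

#' Read a study from PLINK-style text files
#'
#' @param bim_path,fam_path,traw_path file paths.
#' @param covar_path optional covariate TSV (`FID IID <cols...>`).
#' @param study_id cohort label (default: the .fam FID of the first sample).
#' @return a `genotype_study`. Phenotype codes 1/2 decode to control/case;
#'   0 (missing) decodes to `NA` and such samples are excluded from model
#'   fitting downstream.
#' @export
read_study <- function(bim_path, fam_path, traw_path, covar_path = NULL,
                       study_id = NULL) {
  bim <- data.table::fread(bim_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
                           colClasses = list(character = c(1, 2, 5, 6)))
  fam <- data.table::fread(fam_path, header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "phe"),
                           colClasses = list(character = c(1, 2)))
  traw <- data.table::fread(traw_path, header = TRUE)
  if (anyDuplicated(bim$snp_id))
    omniprs_error("duplicate SNP ID in .bim", "omniprs_error_duplicate_snp")
  if (!all(bim$snp_id %in% traw$SNP))
    omniprs_error("SNP(s) listed in .bim absent from .traw",
                  "omniprs_error_alignment")
  if (nrow(traw) != nrow(bim))
    omniprs_error(".bim and .traw disagree on SNP count",
                  "omniprs_error_dimension")
  traw <- traw[match(bim$snp_id, traw$SNP), ]
  dos_cols <- setdiff(names(traw), c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT"))
  if (length(dos_cols) != nrow(fam))
    omniprs_error(".traw sample columns do not match .fam rows",
                  "omniprs_error_dimension")
  geno <- t(as.matrix(traw[, dos_cols, with = FALSE]))
  storage.mode(geno) <- "double"
  if (!all(fam$phe %in% c(0L, 1L, 2L)))
    omniprs_error(sprintf("unknown phenotype code(s): %s",
                          paste(unique(setdiff(fam$phe, 0:2)), collapse = ", ")),
                  "omniprs_error_phenotype")
  phenotype <- ifelse(fam$phe == 0L, NA_integer_, as.integer(fam$phe) - 1L)
  covs <- NULL
  if (!is.null(covar_path)) {
    cv <- data.table::fread(covar_path, header = TRUE)
    if (nrow(cv) != nrow(fam))
      omniprs_error("covariate rows do not match .fam rows",
                    "omniprs_error_dimension")
    covs <- as.matrix(cv[, setdiff(names(cv), c("FID", "IID")), with = FALSE])
  }
  genotype_study(study_id = study_id %||% fam$fid[1],
                 snps = as.data.frame(bim[, c("snp_id", "chrom", "pos", "a1", "a2")]),
                 geno = geno, phenotype = phenotype, covariates = covs,
                 sample_ids = fam$iid)
}

#' Read a BED6 file of gene intervals
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive, so
#' a BED line `chr1 999 2000` becomes the interval `[1000, 2000]`. A missing
#' strand column defaults to `"+"`.
#'
#' @param path BED file path.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  bed <- data.table::fread(path, header = FALSE, fill = TRUE)
  if (ncol(bed) < 4)
    omniprs_error("BED file needs at least 4 columns (chrom, start, end, name)",
                  "omniprs_error_format")
  if (any(bed[[3]] <= bed[[2]]))
    omniprs_error("BED end <= start", "omniprs_error_format")
  strand <- if (ncol(bed) >= 6) as.character(bed[[6]]) else rep("+", nrow(bed))
  strand[!strand %in% c("+", "-")] <- "+"
  data.frame(gene_id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
             start = bed[[2]] + 1, end = bed[[3]], strand = strand,
             stringsAsFactors = FALSE)
}

#' Write gene intervals as BED6
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @param path output path.
#' @export
write_bed <- function(genes, path) {
  data.table::fwrite(
    data.frame(genes$chrom, genes$start - 1, genes$end, genes$gene_id, 0,
               genes$strand),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then one or more tab-separated gene ids.
#' Duplicate genes within a set are deduplicated with a warning. An empty
#' file yields an empty collection.
#'
#' @param path GMT file path.
#' @return named list of character gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    omniprs_error(sprintf("GMT line(s) with fewer than 3 fields: line %s",
                          paste(which(bad), collapse = ", ")),
                  "omniprs_error_format")
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    if (anyDuplicated(genes))
      omniprs_warn(sprintf("duplicate genes in GMT set '%s'; deduplicated", p[1]),
                   "omniprs_warning_gmt_dup")
    unique(genes)
  })
  setNames(sets, vapply(parts, `[[`, "", 1))
}

#' Write gene sets as GMT
#' @param gene_sets named list of character gene-id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], description,
            gene_sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read GWAS summary statistics
#'
#' TSV with header `SNP A1 A2 LNOR SE P N`.
#' @param stats a summary-statistics data.frame (see [gwas()]).
#' @param path file path.
#' @export
write_sumstats <- function(stats, path) {
  data.table::fwrite(
    data.frame(SNP = stats$snp_id, A1 = stats$a1, A2 = stats$a2,
               LNOR = stats$lnor, SE = stats$se, P = stats$p, N = stats$n),
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- data.table::fread(path, header = TRUE)
  data.frame(snp_id = as.character(x$SNP), a1 = as.character(x$A1),
             a2 = as.character(x$A2), lnor = x$LNOR, se = x$SE, p = x$P,
             n = x$N, flagged = FALSE, stringsAsFactors = FALSE)
}

#' QC thresholds
#'
#' Defaults reproduce the standard GWAS consortium chain: SNP missingness
#' < 0.05 before sample removal, subject missingness < 0.02, autosomal
#' heterozygosity deviation |Fhet| < 0.2, SNP missingness < 0.02 after sample
#' removal, case-control missingness difference < 0.02, and Hardy-Weinberg
#' equilibrium p > 1e-6 in controls / p > 1e-10 in cases. All thresholds are
#' retain-if-below (exclusion at >=).
#'
#' @param snp_miss_pre,subj_miss,fhet_abs,snp_miss_post,diff_miss_case_control,hwe_p_controls,hwe_p_cases
#'   threshold values.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_miss_pre = 0.05, subj_miss = 0.02,
                          fhet_abs = 0.2, snp_miss_post = 0.02,
                          diff_miss_case_control = 0.02,
                          hwe_p_controls = 1e-6, hwe_p_cases = 1e-10) {
  structure(list(snp_miss_pre = snp_miss_pre, subj_miss = subj_miss,
                 fhet_abs = fhet_abs, snp_miss_post = snp_miss_post,
                 diff_miss_case_control = diff_miss_case_control,
                 hwe_p_controls = hwe_p_controls, hwe_p_cases = hwe_p_cases),
            class = "qc_thresholds")
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Pearson chi-square with 1 df, no continuity correction. Monomorphic
#' genotype counts fit Hardy-Weinberg trivially (p = 1).
#'
#' @param n0,n1,n2 counts of genotypes carrying 0, 1, 2 copies of A1.
#' @return the upper-tail p-value.
#' @export
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(1)
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Apply the QC filter chain to a study
#'
#' Filters are applied in order: (1) SNPs with missingness >= `snp_miss_pre`;
#' (2) samples with missingness >= `subj_miss` or |Fhet| >= `fhet_abs`, where
#' `Fhet = 1 - observed het / expected het` over the retained SNPs;
#' (3) SNPs with missingness >= `snp_miss_post`; (4) SNPs whose case-control
#' missingness difference >= `diff_miss_case_control`; (5) SNPs failing
#' Hardy-Weinberg equilibrium (chi-square p <= `hwe_p_controls` in controls
#' or <= `hwe_p_cases` in cases).
#'
#' @param study a `genotype_study` with phenotypes present.
#' @param thresholds a [qc_thresholds()].
#' @return list with `study` (filtered) and `report` (data.frame
#'   `filter`, `removed`, `kind`).
#' @export
qc_filter <- function(study, thresholds = qc_thresholds()) {
  g <- study$geno
  report <- data.frame(filter = character(), removed = integer(),
                       kind = character(), stringsAsFactors = FALSE)
  note <- function(filter, removed, kind)
    rbind(report, data.frame(filter = filter, removed = removed, kind = kind,
                             stringsAsFactors = FALSE))

  snp_miss <- colMeans(is.na(g))
  drop_snp <- snp_miss >= thresholds$snp_miss_pre
  report <- note("snp_missingness_pre", sum(drop_snp), "snp")
  g <- g[, !drop_snp, drop = FALSE]
  if (ncol(g) == 0)
    omniprs_error("QC removed every SNP: empty panel", "omniprs_error_empty_panel")

  subj_miss <- rowMeans(is.na(g))
  p_hat <- colMeans(g, na.rm = TRUE) / 2
  exp_het_snp <- 2 * p_hat * (1 - p_hat)
  obs <- !is.na(g)
  exp_het <- (obs %*% exp_het_snp) / rowSums(obs)
  obs_het <- rowMeans(g == 1, na.rm = TRUE)
  fhet <- ifelse(exp_het > 0, 1 - obs_het / exp_het, 0)
  drop_samp <- subj_miss >= thresholds$subj_miss | abs(fhet) >= thresholds$fhet_abs
  report <- note("subject_missingness_or_fhet", sum(drop_samp), "sample")
  keep_samp <- !drop_samp
  g <- g[keep_samp, , drop = FALSE]
  pheno <- study$phenotype[keep_samp]

  snp_miss2 <- colMeans(is.na(g))
  drop_snp2 <- snp_miss2 >= thresholds$snp_miss_post
  report <- note("snp_missingness_post", sum(drop_snp2), "snp")
  g <- g[, !drop_snp2, drop = FALSE]
  if (ncol(g) == 0)
    omniprs_error("QC removed every SNP: empty panel", "omniprs_error_empty_panel")

  is_case <- !is.na(pheno) & pheno == 1L
  is_ctrl <- !is.na(pheno) & pheno == 0L
  miss_case <- colMeans(is.na(g[is_case, , drop = FALSE]))
  miss_ctrl <- colMeans(is.na(g[is_ctrl, , drop = FALSE]))
  drop_diff <- abs(miss_case - miss_ctrl) >= thresholds$diff_miss_case_control
  report <- note("case_control_missingness_diff", sum(drop_diff), "snp")
  g <- g[, !drop_diff, drop = FALSE]
  if (ncol(g) == 0)
    omniprs_error("QC removed every SNP: empty panel", "omniprs_error_empty_panel")

  hwe_fail <- vapply(seq_len(ncol(g)), function(j) {
    gc <- g[is_ctrl, j]; ga <- g[is_case, j]
    p_ctrl <- hwe_chisq_p(sum(gc == 0, na.rm = TRUE), sum(gc == 1, na.rm = TRUE),
                          sum(gc == 2, na.rm = TRUE))
    p_case <- hwe_chisq_p(sum(ga == 0, na.rm = TRUE), sum(ga == 1, na.rm = TRUE),
                          sum(ga == 2, na.rm = TRUE))
    p_ctrl <= thresholds$hwe_p_controls || p_case <= thresholds$hwe_p_cases
  }, logical(1))
  report <- note("hwe_by_status", sum(hwe_fail), "snp")
  g <- g[, !hwe_fail, drop = FALSE]
  if (ncol(g) == 0)
    omniprs_error("QC removed every SNP: empty panel", "omniprs_error_empty_panel")

  keep_ids <- colnames(g)
  out <- genotype_study(
    study_id = study$study_id,
    snps = study$snps[match(keep_ids, study$snps$snp_id), , drop = FALSE],
    geno = g, phenotype = pheno,
    covariates = if (is.null(study$covariates)) NULL
                 else study$covariates[keep_samp, , drop = FALSE],
    sample_ids = study$sample_ids[keep_samp])
  list(study = out, report = report)
}
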