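# Synthetic multi-study case-control genotype generator.
#
# The generator emulates the structure of a multi-cohort case-control GWAS
# panel: several studies of unequal size, hard-call additive genotypes with
# missingness, per-study allele-frequency drift (Balding-Nichols), a
# liability-threshold disease model with an omnigenic effect-size background,
# optional enrichment of effect-size variance in a designated "core" gene set,
# and per-sample covariate columns that act as principal-component surrogates.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults describe a
#' desk-scale panel: 6 studies of unequal size (200-400 samples each), 2000
#' SNPs and 300 genes on a 10 Mb chromosome.
#'
#' @param n_studies number of cohorts.
#' @param cases_per_study,controls_per_study integer vectors of length
#'   `n_studies` giving the ascertained case/control counts of each cohort.
#' @param n_snps,n_genes marker and gene counts.
#' @param chrom_length chromosome length in bp; genes are packed without
#'   overlap, so the total gene length must fit.
#' @param gene_length_range min/max gene length in bp (uniform).
#' @param maf_range min/max ancestral minor-allele frequency (uniform).
#' @param h2_liability narrow-sense heritability on the liability scale, in
#'   `[0, 1)`. Effect sizes are rescaled so that
#'   `sum(2 p (1-p) beta^2) == h2_liability` exactly.
#' @param prevalence population disease prevalence in (0, 1); the liability
#'   threshold is `qnorm(1 - prevalence)`.
#' @param core_set_name name of the gene set whose SNPs receive enriched
#'   effect-size variance.
#' @param core_set_genes,n_control_sets,control_set_genes gene-set sizes: the
#'   core set, and the number/size of non-enriched control sets.
#' @param set_overlap_fraction fraction of each control set drawn from the
#'   core set (0 = disjoint).
#' @param core_enrichment variance multiplier (>= 1) applied to effect sizes
#'   of SNPs mapped to the core set before the global rescaling.
#' @param prop_causal_genic share of `h2_liability` carried by genic SNPs.
#'   `NULL` (default) allocates variance proportionally to the genic/non-genic
#'   SNP counts, i.e. a uniform per-SNP variance; `1` places all liability
#'   variance at genic SNPs.
#' @param study_drift_f Wright's F for Balding-Nichols per-study
#'   allele-frequency drift, in `[0, 0.2]`.
#' @param missing_rate genotype missingness rate, applied uniformly.
#' @param n_covariates number of simulated covariate columns (study-correlated
#'   Gaussians standing in for principal components).
#' @param upstream_bp,downstream_bp genic margins used when the generator
#'   classifies SNPs (see [genic_margins()]).
#' @param seed root seed; all stage seeds are derived from it with
#'   [derive_seed()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_studies = 6L,
                       cases_per_study = c(160L, 140L, 120L, 100L, 90L, 80L),
                       controls_per_study = c(240L, 210L, 180L, 150L, 130L, 120L),
                       n_snps = 2000L,
                       n_genes = 300L,
                       chrom_length = 1e7,
                       gene_length_range = c(2000, 20000),
                       maf_range = c(0.05, 0.5),
                       h2_liability = 0.3,
                       prevalence = 0.1,
                       core_set_name = "core",
                       core_set_genes = 50L,
                       n_control_sets = 2L,
                       control_set_genes = 50L,
                       set_overlap_fraction = 0,
                       core_enrichment = 1,
                       prop_causal_genic = NULL,
                       study_drift_f = 0.02,
                       missing_rate = 0.01,
                       n_covariates = 3L,
                       upstream_bp = 5000,
                       downstream_bp = 1000,
                       seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              cases_per_study = as.integer(cases_per_study),
              controls_per_study = as.integer(controls_per_study),
              n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
              chrom_length = chrom_length,
              gene_length_range = gene_length_range,
              maf_range = maf_range,
              h2_liability = h2_liability, prevalence = prevalence,
              core_set_name = core_set_name,
              core_set_genes = as.integer(core_set_genes),
              n_control_sets = as.integer(n_control_sets),
              control_set_genes = as.integer(control_set_genes),
              set_overlap_fraction = set_overlap_fraction,
              core_enrichment = core_enrichment,
              prop_causal_genic = prop_causal_genic,
              study_drift_f = study_drift_f,
              missing_rate = missing_rate,
              n_covariates = as.integer(n_covariates),
              margins = genic_margins(upstream_bp, downstream_bp),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L)
    omniprs_error("at least 1 gene required", "omniprs_error_config")
  if (cfg$n_snps < 1L)
    omniprs_error("at least 1 SNP required", "omniprs_error_config")
  if (length(cfg$cases_per_study) != cfg$n_studies ||
      length(cfg$controls_per_study) != cfg$n_studies)
    omniprs_error("cases_per_study and controls_per_study must have length n_studies",
                  "omniprs_error_config")
  if (any(cfg$cases_per_study < 1L) || any(cfg$controls_per_study < 1L))
    omniprs_error("per-study case and control counts must be >= 1",
                  "omniprs_error_config")
  if (cfg$h2_liability < 0 || cfg$h2_liability >= 1)
    omniprs_error("h2_liability must lie in [0, 1)", "omniprs_error_config")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    omniprs_error("prevalence must lie in (0, 1)", "omniprs_error_config")
  if (cfg$core_enrichment < 1)
    omniprs_error("core_enrichment must be >= 1", "omniprs_error_config")
  if (!is.null(cfg$prop_causal_genic) &&
      (cfg$prop_causal_genic < 0 || cfg$prop_causal_genic > 1))
    omniprs_error("prop_causal_genic must lie in [0, 1]", "omniprs_error_config")
  if (cfg$study_drift_f < 0 || cfg$study_drift_f > 0.2)
    omniprs_error("study_drift_f must lie in [0, 0.2]", "omniprs_error_config")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    omniprs_error("missing_rate must lie in [0, 1)", "omniprs_error_config")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    omniprs_error("maf_range must satisfy 0 < min <= max <= 0.5",
                  "omniprs_error_config")
  invisible(cfg)
}

#' Simulate gene annotation and SNP positions
#'
#' Packs `n_genes` non-overlapping genes with random strands onto a single
#' chromosome and scatters `n_snps` marker positions uniformly over it.
#'
#' @param cfg a [sim_config()].
#' @return a list with class `sim_annotation`: `genes` (data.frame `gene_id`,
#'   `chrom`, `start`, `end`, `strand`; 1-based inclusive) and `snps`
#'   (data.frame `snp_id`, `chrom`, `pos`, `a1`, `a2`). Attributes
#'   `n_genic`/`n_nongenic` carry the genic split under `cfg$margins`.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  total_max_len <- cfg$n_genes * cfg$gene_length_range[2]
  with_seed(derive_seed(cfg$seed, "annotation"), {
    lens <- round(runif(cfg$n_genes, cfg$gene_length_range[1],
                        cfg$gene_length_range[2]))
    if (sum(lens) >= cfg$chrom_length)
      omniprs_error(sprintf(
        "cannot pack %d genes (total %.0f bp) onto a %.0f bp chromosome",
        cfg$n_genes, sum(lens), cfg$chrom_length), "omniprs_error_config")
    free <- cfg$chrom_length - sum(lens)
    gap_frac <- diff(c(0, sort(runif(cfg$n_genes)), 1))
    gaps <- floor(gap_frac * free)
    starts <- cumsum(c(1, head(lens, -1))) + cumsum(gaps[-length(gaps)])
    ends <- starts + lens - 1
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
      chrom = "1", start = starts, end = ends, strand = strand,
      stringsAsFactors = FALSE)
    pos <- sort(sample.int(cfg$chrom_length, cfg$n_snps))
    alleles <- c("A", "C", "G", "T")
    a1 <- sample(alleles, cfg$n_snps, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1), "")
    snps <- data.frame(
      snp_id = sprintf("snp%06d", seq_len(cfg$n_snps)),
      chrom = "1", pos = pos, a1 = a1, a2 = unname(a2),
      stringsAsFactors = FALSE)
  })
  ann <- structure(list(genes = genes, snps = snps), class = "sim_annotation")
  cls <- classify_genic(snps, genes, cfg$margins)
  attr(ann, "n_genic") <- sum(cls$genic)
  attr(ann, "n_nongenic") <- sum(!cls$genic)
  if (attr(ann, "n_genic") == 0L || attr(ann, "n_nongenic") == 0L)
    omniprs_error(
      "annotation has no genic or no non-genic SNPs; adjust chrom_length/n_genes",
      "omniprs_error_config")
  ann
}

#' Build the designated core set and non-enriched control gene sets
#'
#' @param annotation a [simulate_annotation()] result.
#' @param cfg a [sim_config()].
#' @return named list of character gene-id vectors; the element named
#'   `cfg$core_set_name` is the core set.
#' @export
make_gene_sets <- function(annotation, cfg) {
  if (cfg$core_set_genes > cfg$n_genes || cfg$control_set_genes > cfg$n_genes)
    omniprs_error("requested gene-set size exceeds number of genes",
                  "omniprs_error_config")
  gene_ids <- annotation$genes$gene_id
  n_shared <- floor(cfg$set_overlap_fraction * cfg$control_set_genes)
  n_fresh <- cfg$control_set_genes - n_shared
  if (cfg$core_set_genes + cfg$n_control_sets * n_fresh > cfg$n_genes)
    omniprs_error("not enough genes for the requested non-overlapping sets",
                  "omniprs_error_config")
  with_seed(derive_seed(cfg$seed, "gene_sets"), {
    core <- sort(sample(gene_ids, cfg$core_set_genes))
    available <- setdiff(gene_ids, core)
    controls <- lapply(seq_len(cfg$n_control_sets), function(i) {
      shared <- if (n_shared > 0) sample(core, min(n_shared, length(core)))
                else character(0)
      fresh <- sample(available, n_fresh)
      # keep control sets mutually disjoint: overlap is only ever with core,
      # and only by the configured fraction
      available <<- setdiff(available, fresh)
      sort(c(shared, fresh))
    })
  })
  sets <- c(list(core), controls)
  names(sets) <- c(cfg$core_set_name,
                   sprintf("control%d", seq_len(cfg$n_control_sets)))
  sets
}

#' Simulate the true genetic architecture
#'
#' Draws ancestral allele frequencies and zero-mean Gaussian liability-scale
#' effect sizes for every SNP (the omnigenic background), multiplies the
#' effect-size variance of core-set SNPs by `core_enrichment`, and rescales so
#' that the total liability variance contributed by genotypes,
#' `sum(2 p (1-p) beta^2)`, equals `h2_liability` exactly.
#'
#' @param cfg a [sim_config()].
#' @param annotation a [simulate_annotation()] result.
#' @param gene_sets gene sets from [make_gene_sets()]; must contain
#'   `cfg$core_set_name` unless `core_enrichment == 1`.
#' @return object of class `true_architecture`: data.frame fields `snp_id`,
#'   `beta`, `core_member`, `genic`, `ancestral_maf`, plus attributes
#'   `liability_threshold` and `h2_liability`.
#' @export
simulate_effects <- function(cfg, annotation, gene_sets = NULL) {
  m <- cfg$n_snps
  cls <- classify_genic(annotation$snps, annotation$genes, cfg$margins)
  core_member <- rep(FALSE, m)
  if (cfg$core_enrichment > 1 || !is.null(gene_sets)) {
    if (is.null(gene_sets) || is.null(gene_sets[[cfg$core_set_name]])) {
      if (cfg$core_enrichment > 1)
        omniprs_error(sprintf("no gene set named '%s' supplied but core_enrichment > 1",
                              cfg$core_set_name), "omniprs_error_config")
    } else {
      core_snps <- snps_for_gene_set(gene_sets[[cfg$core_set_name]], cls)
      core_member <- annotation$snps$snp_id %in% core_snps
    }
  }
  with_seed(derive_seed(cfg$seed, "effects"), {
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    beta <- rnorm(m)
  })
  beta[core_member] <- beta[core_member] * sqrt(cfg$core_enrichment)
  vterm <- 2 * maf * (1 - maf) * beta^2
  genic <- cls$genic
  scale_group <- function(b, vt, target) {
    tot <- sum(vt)
    if (target == 0 || tot == 0) rep(0, length(b)) else b * sqrt(target / tot)
  }
  if (is.null(cfg$prop_causal_genic)) {
    # uniform omnigenic background: one global rescale, so the core /
    # non-core effect-size variance ratio equals core_enrichment exactly
    beta <- scale_group(beta, vterm, cfg$h2_liability)
  } else {
    # explicit split of liability variance between genic and non-genic SNPs
    prop <- cfg$prop_causal_genic
    beta[genic] <- scale_group(beta[genic], vterm[genic],
                               cfg$h2_liability * prop)
    beta[!genic] <- scale_group(beta[!genic], vterm[!genic],
                                cfg$h2_liability * (1 - prop))
  }
  structure(
    data.frame(snp_id = annotation$snps$snp_id, beta = beta,
               core_member = core_member, genic = genic,
               ancestral_maf = maf, stringsAsFactors = FALSE),
    liability_threshold = qnorm(1 - cfg$prevalence),
    h2_liability = cfg$h2_liability,
    prevalence = cfg$prevalence,
    class = c("true_architecture", "data.frame"))
}

#' Simulate one ascertained case-control study
#'
#' Study allele frequencies are drawn from a Balding-Nichols Beta distribution
#' around the ancestral frequencies with drift parameter `drift_f`; genotypes
#' are Hardy-Weinberg draws at the study frequencies. Liability is the
#' centred genetic score standardized to variance `h2` plus Gaussian noise of
#' variance `1 - h2`; a sample is a case when liability exceeds the threshold.
#' Sampling batches are rejected until the exact case and control counts are
#' reached (ascertainment), then missingness and covariates are applied.
#'
#' @param arch a [simulate_effects()] result.
#' @param snps SNP annotation data.frame (from `annotation$snps`).
#' @param n_case,n_control ascertained counts (>= 1).
#' @param drift_f Balding-Nichols F.
#' @param missing_rate genotype missing rate.
#' @param n_covariates number of covariate columns.
#' @param seed stage seed for this study.
#' @param study_id study label.
#' @param max_batches rejection-sampling cap; exceeded => error naming the cap.
#' @return a `genotype_study` object (see [genotype_study()]).
#' @export
simulate_study <- function(arch, snps, n_case, n_control,
                           drift_f = 0.02, missing_rate = 0.01,
                           n_covariates = 3L, seed = 1L,
                           study_id = "study1", max_batches = 200L) {
  stopifnot(n_case >= 1, n_control >= 1)
  m <- nrow(arch)
  h2 <- attr(arch, "h2_liability")
  thr <- attr(arch, "liability_threshold")
  prev <- attr(arch, "prevalence")
  with_seed(as.integer(seed), {
    p <- arch$ancestral_maf
    if (drift_f > 0) {
      a <- p * (1 - drift_f) / drift_f
      b <- (1 - p) * (1 - drift_f) / drift_f
      p_s <- rbeta(m, a, b)
    } else p_s <- p
    vterm <- 2 * p_s * (1 - p_s) * arch$beta^2
    v <- sum(vterm)
    gscale <- if (h2 > 0 && v > 0) sqrt(h2 / v) else 0
    # batch size targets the scarcer stratum (cases under low prevalence)
    batch <- max(200L, ceiling(1.5 * n_case / prev))
    got_case <- 0L; got_control <- 0L
    case_rows <- vector("list", 0); control_rows <- vector("list", 0)
    iter <- 0L
    while ((got_case < n_case || got_control < n_control)) {
      iter <- iter + 1L
      if (iter > max_batches)
        omniprs_error(sprintf(
          "rejection sampling exceeded the cap of %d batches (prevalence too extreme?)",
          max_batches), "omniprs_error_sampling")
      g <- matrix(rbinom(batch * m, 2L, rep(p_s, each = batch)),
                  nrow = batch, ncol = m)
      gc_score <- as.numeric(g %*% arch$beta) - sum(2 * p_s * arch$beta)
      liab <- gc_score * gscale + rnorm(batch, sd = sqrt(1 - h2))
      is_case <- liab > thr
      if (got_case < n_case && any(is_case)) {
        take <- which(is_case)[seq_len(min(sum(is_case), n_case - got_case))]
        case_rows <- c(case_rows, list(g[take, , drop = FALSE]))
        got_case <- got_case + length(take)
      }
      if (got_control < n_control && any(!is_case)) {
        take <- which(!is_case)[seq_len(min(sum(!is_case), n_control - got_control))]
        control_rows <- c(control_rows, list(g[take, , drop = FALSE]))
        got_control <- got_control + length(take)
      }
    }
    geno <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
    phenotype <- c(rep(1L, n_case), rep(0L, n_control))
    n <- n_case + n_control
    if (missing_rate > 0) {
      miss <- runif(n * m) < missing_rate
      geno[matrix(miss, nrow = n)] <- NA_integer_
    }
    covs <- NULL
    if (n_covariates > 0) {
      mu <- rnorm(n_covariates, sd = 0.7)
      covs <- sapply(seq_len(n_covariates), function(k) mu[k] + rnorm(n))
      colnames(covs) <- sprintf("COV%d", seq_len(n_covariates))
    }
  })
  storage.mode(geno) <- "double"
  genotype_study(study_id = study_id, snps = snps, geno = geno,
                 phenotype = phenotype, covariates = covs)
}

#' Construct a genotype study container
#'
#' @param study_id cohort label.
#' @param snps data.frame `snp_id`, `chrom`, `pos`, `a1`, `a2` in panel order;
#'   the dosage matrix counts copies of `a1`.
#' @param geno numeric matrix, samples x SNPs, values 0/1/2 or `NA`.
#' @param phenotype integer vector: 1 = case, 0 = control, `NA` = missing.
#' @param covariates numeric matrix (samples x k) or `NULL`.
#' @param sample_ids optional character sample IDs (default generated).
#' @return an object of class `genotype_study`.
#' @export
genotype_study <- function(study_id, snps, geno, phenotype,
                           covariates = NULL, sample_ids = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  if (m != nrow(snps))
    omniprs_error("dosage matrix columns do not match SNP table",
                  "omniprs_error_dimension")
  if (length(phenotype) != n)
    omniprs_error("phenotype length does not match dosage matrix rows",
                  "omniprs_error_dimension")
  if (!is.null(covariates) && nrow(covariates) != n)
    omniprs_error("covariate rows do not match dosage matrix rows",
                  "omniprs_error_dimension")
  if (anyDuplicated(snps$snp_id))
    omniprs_error("duplicate SNP IDs in panel", "omniprs_error_duplicate_snp")
  if (is.null(sample_ids))
    sample_ids <- sprintf("%s_%04d", study_id, seq_len(n))
  dimnames(geno) <- list(sample_ids, snps$snp_id)
  structure(list(study_id = study_id, snps = snps, geno = geno,
                 phenotype = as.integer(phenotype),
                 covariates = covariates, sample_ids = sample_ids),
            class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  cat(sprintf("<genotype_study '%s': %d samples (%d cases / %d controls), %d SNPs, %d covariates>\n",
              x$study_id, nrow(x$geno), sum(x$phenotype == 1L, na.rm = TRUE),
              sum(x$phenotype == 0L, na.rm = TRUE), ncol(x$geno),
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' Simulate a full multi-study panel
#'
#' Convenience wrapper: annotation, gene sets, true architecture and all
#' studies, each stage under its own derived seed.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_bundle` with elements `cfg`, `annotation`,
#'   `gene_sets`, `arch`, `studies` (named list of `genotype_study`).
#' @export
simulate_cohorts <- function(cfg) {
  annotation <- simulate_annotation(cfg)
  gene_sets <- make_gene_sets(annotation, cfg)
  arch <- simulate_effects(cfg, annotation, gene_sets)
  studies <- lapply(seq_len(cfg$n_studies), function(s) {
    simulate_study(arch, annotation$snps,
                   n_case = cfg$cases_per_study[s],
                   n_control = cfg$controls_per_study[s],
                   drift_f = cfg$study_drift_f,
                   missing_rate = cfg$missing_rate,
                   n_covariates = cfg$n_covariates,
                   seed = derive_seed(cfg$seed, "study", s),
                   study_id = sprintf("study%d", s))
  })
  names(studies) <- vapply(studies, `[[`, "", "study_id")
  structure(list(cfg = cfg, annotation = annotation, gene_sets = gene_sets,
                 arch = arch, studies = studies),
            class = "sim_bundle")
}
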