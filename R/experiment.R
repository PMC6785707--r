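# End-to-end experiment runner driven by a YAML configuration.

experiment_keys <- c("seed", "sim", "qc", "gene_sets", "prune", "grid",
                     "loo", "permutations", "alpha", "floor", "weight",
                     "genomewide")

#' Run a configured end-to-end experiment
#'
#' Executes: simulation of the multi-study panel, optional QC, the
#' leave-one-out PRS analysis per gene set, and (when configured) the
#' phenotype-permutation null and the random genic/non-genic floor analysis.
#' All tables are written as TSV under `out_dir` together with a manifest
#' recording seeds and parameters.
#'
#' Recognized configuration keys: `seed`; `sim` (fields of [sim_config()]);
#' `qc` (logical); `gene_sets` (names to analyze; default all simulated
#' sets); `prune` (`window_snps`, `step_snps`, `r2_max`); `grid` (cutoffs);
#' `loo` (logical); `permutations` (count; omit to skip); `alpha`; `floor`
#' (`n_sets`, `set_size`, `r2_max_pool`; omit to skip); `weight`
#' (`total`/`effective`); `genomewide` (logical: add an unrestricted,
#' unpruned genome-wide score analysis).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every computed result.
#' @export
run_experiment <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(cfg), experiment_keys)
  if (length(unknown))
    omniprs_error(sprintf("unknown configuration key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "omniprs_error_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)

  sim_args <- cfg$sim %||% list()
  sim_args$seed <- seed
  scfg <- do.call(sim_config, sim_args)
  bundle <- simulate_cohorts(scfg)
  write_bed(bundle$annotation$genes, file.path(out_dir, "genes.bed"))
  write_gmt(bundle$gene_sets, file.path(out_dir, "gene_sets.gmt"))
  data.table::fwrite(as.data.frame(bundle$arch),
                     file.path(out_dir, "truth_architecture.tsv"), sep = "\t")
  for (nm in names(bundle$studies))
    write_study(bundle$studies[[nm]], file.path(out_dir, nm))

  studies <- bundle$studies
  qc_reports <- NULL
  if (isTRUE(cfg$qc)) {
    qcs <- lapply(studies, qc_filter)
    # keep the SNP panel common across studies after per-study QC
    kept <- Reduce(intersect, lapply(qcs, function(q) q$study$snps$snp_id))
    studies <- lapply(qcs, function(q) restrict_snps(q$study, kept))
    qc_reports <- do.call(rbind, lapply(names(qcs), function(nm)
      cbind(study = nm, qcs[[nm]]$report)))
    data.table::fwrite(qc_reports, file.path(out_dir, "qc_report.tsv"), sep = "\t")
  }

  cls <- classify_genic(studies[[1]]$snps, bundle$annotation$genes, scfg$margins)
  prune <- do.call(prune_params, cfg$prune %||% list())
  grid <- if (is.null(cfg$grid)) threshold_grid() else threshold_grid(cfg$grid)
  weight <- cfg$weight %||% "total"
  alpha <- cfg$alpha %||% 0.05

  results <- list(bundle = bundle, qc = qc_reports)
  if (!identical(cfg$loo, FALSE)) {
    set_names <- cfg$gene_sets %||% names(bundle$gene_sets)
    snp_sets <- lapply(bundle$gene_sets[set_names], snps_for_gene_set, cls)
    loo <- loo_run_multi(studies, snp_sets, grid = grid, prune = prune,
                         weight = weight)
    results$loo <- loo
    records <- do.call(rbind, lapply(names(loo), function(nm)
      cbind(gene_set = nm, loo[[nm]]$records)))
    data.table::fwrite(records, file.path(out_dir, "loo_records.tsv"), sep = "\t")
    meta_tab <- do.call(rbind, lapply(names(loo), function(nm) {
      m <- loo[[nm]]$meta
      data.frame(gene_set = nm, n_snps = length(snp_sets[[nm]]),
                 z_meta = m$z_meta, p_meta = m$p_meta,
                 k_significant = m$k_significant, n_studies = m$n_studies,
                 r2_median = m$r2_median, r2_iqr = m$r2_iqr,
                 r2_min = m$r2_range[1], r2_max = m$r2_range[2])
    }))
    data.table::fwrite(meta_tab, file.path(out_dir, "meta_report.tsv"), sep = "\t")
  }
  if (isTRUE(cfg$genomewide)) {
    gw <- loo_run(studies, studies[[1]]$snps$snp_id, grid = grid,
                  prune = NULL, weight = weight)
    results$genomewide <- gw
    data.table::fwrite(gw$records, file.path(out_dir, "genomewide_records.tsv"),
                       sep = "\t")
  }
  if (!is.null(cfg$permutations)) {
    core_set <- snps_for_gene_set(bundle$gene_sets[[scfg$core_set_name]], cls)
    perm <- permutation_experiment(studies, core_set,
                                   n_permutations = as.integer(cfg$permutations),
                                   alpha = alpha,
                                   seed = derive_seed(seed, "permutation"),
                                   grid = grid, prune = prune, weight = weight)
    results$permutation <- perm
    data.table::fwrite(
      data.frame(permutation = seq_along(perm$p_meta), p_meta = perm$p_meta,
                 reject = perm$p_meta < alpha),
      file.path(out_dir, "permutation_report.tsv"), sep = "\t")
  }
  if (!is.null(cfg$floor)) {
    fl <- floor_analysis(
      studies, cls,
      n_sets = as.integer(cfg$floor$n_sets %||% 50L),
      set_size = as.integer(cfg$floor$set_size %||% 5000L),
      pool_prune = prune_params(prune$window_snps, prune$step_snps,
                                cfg$floor$r2_max_pool %||% 0.01),
      seed = derive_seed(seed, "floor"), grid = grid, prune = prune,
      weight = weight)
    results$floor <- fl
    floor_tab <- do.call(rbind, lapply(c("genic", "nongenic"), function(pool)
      data.frame(pool = pool,
                 p_median = fl[[pool]]$p_median,
                 p_min = fl[[pool]]$p_range[1], p_max = fl[[pool]]$p_range[2],
                 r2_median = fl[[pool]]$r2_median,
                 r2_min = fl[[pool]]$r2_range[1],
                 r2_max = fl[[pool]]$r2_range[2])))
    data.table::fwrite(floor_tab, file.path(out_dir, "floor_report.tsv"), sep = "\t")
  }
  manifest <- list(seed = seed, package_version = as.character(
                     utils::packageVersion("omniprs")),
                   config = cfg)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}

# Restrict a study to a SNP subset (panel order preserved).
restrict_snps <- function(study, snp_ids) {
  keep <- study$snps$snp_id %in% snp_ids
  genotype_study(study$study_id, study$snps[keep, , drop = FALSE],
                 study$geno[, keep, drop = FALSE], study$phenotype,
                 covariates = study$covariates, sample_ids = study$sample_ids)
}
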