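#!/usr/bin/env Rscript
# Leave-one-out gene-set PRS analysis on the simulated panel: for each study
# in turn, a pooled training GWAS on the remaining studies, risk-allele
# orientation, LD pruning (50-SNP window, step 5, r2 < 0.25), restriction to
# the gene set, in-training selection among nine p-value cutoffs, scoring of
# the held-out study, and nested logistic evaluation; held-out results are
# combined with sample-size-weighted Stouffer's Z. Run for the enriched core
# set and two non-enriched control sets.

library(omniprs)

cfg <- sim_config(seed = 42L, core_enrichment = 10)
bundle <- simulate_cohorts(cfg)   # same seed => same panel as 01
cls <- classify_genic(bundle$annotation$snps, bundle$annotation$genes,
                      cfg$margins)
snp_sets <- lapply(bundle$gene_sets, snps_for_gene_set, cls)

res <- loo_run_multi(bundle$studies, snp_sets)

records <- do.call(rbind, lapply(names(res), function(nm)
  cbind(gene_set = nm, res[[nm]]$records)))
meta_tab <- do.call(rbind, lapply(names(res), function(nm) {
  m <- res[[nm]]$meta
  data.frame(gene_set = nm, n_snps = length(snp_sets[[nm]]),
             z_meta = m$z_meta, p_meta = m$p_meta,
             k_significant = m$k_significant, n_studies = m$n_studies,
             r2_median = m$r2_median, r2_iqr = m$r2_iqr,
             r2_min = m$r2_range[1], r2_max = m$r2_range[2])
}))

dir.create("results", showWarnings = FALSE)
data.table::fwrite(records, "results/loo_records.tsv", sep = "\t")
data.table::fwrite(meta_tab, "results/meta_report.tsv", sep = "\t")

cat("Per-set meta-analysis over", meta_tab$n_studies[1], "held-out studies:\n")
for (i in seq_len(nrow(meta_tab)))
  cat(sprintf("  %-9s %4d SNPs  Stouffer p = %.3g  (%d/%d held-out sets p < 0.05, median nested R2 = %.4f)\n",
              meta_tab$gene_set[i], meta_tab$n_snps[i], meta_tab$p_meta[i],
              meta_tab$k_significant[i], meta_tab$n_studies[i],
              meta_tab$r2_median[i]))
cat("The enriched core set should dominate both control sets.\n")
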