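#!/usr/bin/env Rscript
# Experiment-wise permutation null: permute case/control labels within each
# study 100 times and rerun the entire leave-one-out pipeline (training GWAS
# included) on the core gene set, recording the fraction of permutations
# whose Stouffer meta p falls below 0.05. Run on a no-enrichment panel at a
# reduced per-study sample size (calibration needs no power).

library(omniprs)

cfg <- sim_config(seed = 42L,
                  cases_per_study = c(100L, 90L, 85L, 75L, 70L, 60L),
                  controls_per_study = c(120L, 110L, 105L, 95L, 90L, 80L),
                  core_enrichment = 1)
bundle <- simulate_cohorts(cfg)
cls <- classify_genic(bundle$annotation$snps, bundle$annotation$genes,
                      cfg$margins)
core <- snps_for_gene_set(bundle$gene_sets$core, cls)

perm <- permutation_experiment(bundle$studies, core, n_permutations = 100L,
                               alpha = 0.05, seed = 43L)

dir.create("results", showWarnings = FALSE)
data.table::fwrite(
  data.frame(permutation = seq_along(perm$p_meta), p_meta = perm$p_meta,
             reject = perm$p_meta < 0.05),
  "results/permutation_report.tsv", sep = "\t")

cat(sprintf("Experiment-wise rejections at alpha = 0.05: %d/%d (%.0f%%), exact 95%% CI [%.3f, %.3f]\n",
            perm$n_reject, perm$n_permutations,
            100 * perm$rejection_fraction, perm$ci[1], perm$ci[2]))
cat("A calibrated experiment-wise null keeps this near 5%. Note that the\n")
cat("held-out z-scores of different leave-one-out iterations share training\n")
cat("data, which correlates them positively; see the methods vignette for\n")
cat("what this does to the Stouffer combination at small cohort counts.\n")
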