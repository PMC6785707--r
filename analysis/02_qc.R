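#!/usr/bin/env Rscript
# Genotype quality control per study, reading the panel back from the
# PLINK-style text files written by 01_simulate_cohorts.R: SNP missingness
# (pre), subject missingness and |Fhet|, SNP missingness (post),
# case-control differential missingness, and Hardy-Weinberg equilibrium by
# affection status. Writes per-filter exclusion counts to results/qc_report.tsv.

library(omniprs)

data_dir <- "results/data"
studies <- sub("\\.bim$", "", list.files(data_dir, pattern = "\\.bim$"))

reports <- lapply(studies, function(nm) {
  st <- read_study(file.path(data_dir, paste0(nm, ".bim")),
                   file.path(data_dir, paste0(nm, ".fam")),
                   file.path(data_dir, paste0(nm, ".traw")),
                   covar_path = file.path(data_dir, paste0(nm, ".covar")))
  res <- qc_filter(st)
  cat(sprintf("%s: %d -> %d SNPs, %d -> %d samples\n", nm,
              ncol(st$geno), ncol(res$study$geno),
              nrow(st$geno), nrow(res$study$geno)))
  cbind(study = nm, res$report)
})

report <- do.call(rbind, reports)
dir.create("results", showWarnings = FALSE)
data.table::fwrite(report, "results/qc_report.tsv", sep = "\t")
cat(sprintf("Total exclusions across studies: %d (details in results/qc_report.tsv)\n",
            sum(report$removed)))
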