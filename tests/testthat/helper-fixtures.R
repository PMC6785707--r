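# Deterministic fixtures and independent oracles shared across tests.

# Desk-scale panel kept small so pipeline tests stay fast.
tiny_config <- function(seed = 101L, ...) {
  args <- list(n_studies = 4L,
               cases_per_study = c(45L, 40L, 35L, 30L),
               controls_per_study = c(55L, 50L, 45L, 40L),
               n_snps = 400L, n_genes = 60L, chrom_length = 2e6,
               gene_length_range = c(2000, 12000),
               core_set_genes = 15L, control_set_genes = 15L,
               seed = seed)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(sim_config, args)
}

# Bundles are cached per (seed, overrides) so repeated tests reuse them.
tiny_bundle <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 101L, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_cohorts(tiny_config(seed, ...))
    cache[[key]]
  }
})

# A small hand-buildable study, genotypes HWE at given frequencies.
make_study <- function(n = 40, m = 12, seed = 1, maf = NULL,
                       missing_rate = 0, study_id = "s1") {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.2, 0.5)
  geno <- sapply(maf, function(p) rbinom(n, 2, p))
  if (missing_rate > 0)
    geno[matrix(runif(n * m) < missing_rate, n)] <- NA
  storage.mode(geno) <- "double"
  snps <- data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = "1",
                     pos = sort(sample.int(1e6, m)),
                     a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  genotype_study(study_id, snps, geno, rbinom(n, 1, 0.5),
                 covariates = matrix(rnorm(n), ncol = 1,
                                     dimnames = list(NULL, "COV1")))
}

# Brute-force pruning oracle: within each window, repeatedly rescan all
# retained pairs in genomic order and remove the later SNP of the first
# violating pair, until no pair violates. Independent of ld_prune().
prune_oracle <- function(geno, window, step, r2max) {
  m <- ncol(geno)
  kept <- rep(TRUE, m)
  pair_r2 <- function(i, j) {
    a <- geno[, i]; b <- geno[, j]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 2 || var(a) == 0 || var(b) == 0) return(0)
    cor(a, b)^2
  }
  for (start in seq(1, m, by = step)) {
    end <- min(start + window - 1, m)
    repeat {
      idx <- (start:end)[kept[start:end]]
      removed <- FALSE
      if (length(idx) >= 2) {
        for (ii in seq_len(length(idx) - 1)) {
          for (jj in (ii + 1):length(idx)) {
            if (pair_r2(idx[ii], idx[jj]) > r2max) {
              kept[idx[jj]] <- FALSE
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
      if (!removed) break
    }
    if (end == m) break
  }
  colnames(geno)[kept]
}
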