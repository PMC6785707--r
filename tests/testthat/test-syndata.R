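test_that("degenerate configurations are rejected", {
  expect_error(tiny_config(n_genes = 0L), class = "omniprs_error_config")
  expect_error(tiny_config(h2_liability = 1.2), class = "omniprs_error_config")
  expect_error(tiny_config(cases_per_study = c(10L, 10L)),
               class = "omniprs_error_config")
  expect_error(tiny_config(prevalence = 0), class = "omniprs_error_config")
})

test_that("gene packing produces disjoint in-bounds intervals and fails when impossible", {
  cfg <- sim_config(n_genes = 10L, gene_length_range = c(10000, 10000),
                    chrom_length = 1e6, n_snps = 100L, core_set_genes = 5L,
                    control_set_genes = 5L, seed = 3L)
  ann <- simulate_annotation(cfg)
  g <- ann$genes[order(ann$genes$start), ]
  expect_equal(nrow(g), 10)
  expect_true(all(g$start >= 1 & g$end <= 1e6))
  expect_true(all(g$start[-1] > g$end[-10]))          # disjoint
  expect_true(all(g$end - g$start + 1 == 10000))
  expect_error(
    simulate_annotation(sim_config(n_genes = 200L,
                                   gene_length_range = c(10000, 10000),
                                   chrom_length = 1e6, n_snps = 100L,
                                   core_set_genes = 5L, control_set_genes = 5L)),
    class = "omniprs_error_config")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 77L)
  b1 <- simulate_cohorts(cfg)
  b2 <- simulate_cohorts(cfg)
  expect_identical(b1$annotation, b2$annotation)
  expect_identical(b1$gene_sets, b2$gene_sets)
  expect_identical(b1$arch, b2$arch)
  expect_identical(b1$studies, b2$studies)
  # serialized level: written files byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  write_study(b1$studies[[1]], file.path(d1, "s"))
  write_study(b2$studies[[1]], file.path(d2, "s"))
  for (ext in c(".bim", ".fam", ".traw"))
    expect_identical(readLines(file.path(d1, paste0("s", ext))),
                     readLines(file.path(d2, paste0("s", ext))))
})

test_that("effect sizes satisfy the liability-variance normalization and enrichment contrast", {
  cfg <- tiny_config(seed = 5L, n_snps = 2000L, n_genes = 150L,
                     chrom_length = 6e6, core_set_genes = 40L)
  ann <- simulate_annotation(cfg)
  sets <- make_gene_sets(ann, cfg)
  arch <- simulate_effects(cfg, ann, sets)
  expect_equal(sum(2 * arch$ancestral_maf * (1 - arch$ancestral_maf) * arch$beta^2),
               cfg$h2_liability, tolerance = 1e-12)
  # h2 = 0 => null architecture
  cfg0 <- tiny_config(seed = 5L, h2_liability = 0)
  ann0 <- simulate_annotation(cfg0)
  arch0 <- simulate_effects(cfg0, ann0, make_gene_sets(ann0, cfg0))
  expect_true(all(arch0$beta == 0))
  # core_enrichment = 1: variance ratio within F sampling bounds
  v_core <- var(arch$beta[arch$core_member])
  v_rest <- var(arch$beta[!arch$core_member])
  k1 <- sum(arch$core_member) - 1; k2 <- sum(!arch$core_member) - 1
  band <- qf(c(0.0005, 0.9995), k1, k2)
  expect_gt(v_core / v_rest, band[1])
  expect_lt(v_core / v_rest, band[2])
  # core_enrichment = 10: ratio near 10 within the same sampling bounds
  cfgE <- tiny_config(seed = 5L, n_snps = 2000L, n_genes = 150L,
                      chrom_length = 6e6, core_set_genes = 40L,
                      core_enrichment = 10)
  archE <- simulate_effects(cfgE, ann, sets)
  ratio <- var(archE$beta[archE$core_member]) / var(archE$beta[!archE$core_member])
  expect_gt(ratio, 10 * band[1])
  expect_lt(ratio, 10 * band[2])
})

test_that("liability model hits the configured prevalence before ascertainment", {
  cfg <- tiny_config(seed = 9L, prevalence = 0.2, study_drift_f = 0)
  ann <- simulate_annotation(cfg)
  arch <- simulate_effects(cfg, ann, make_gene_sets(ann, cfg))
  # independent Monte-Carlo oracle of the generative equations
  set.seed(42)
  nrep <- 4000
  p <- arch$ancestral_maf
  g <- sapply(p, function(pp) rbinom(nrep, 2, pp))
  gs <- as.numeric(g %*% arch$beta) - sum(2 * p * arch$beta)
  v <- sum(2 * p * (1 - p) * arch$beta^2)
  liab <- gs * sqrt(cfg$h2_liability / v) +
    rnorm(nrep, sd = sqrt(1 - cfg$h2_liability))
  frac <- mean(liab > attr(arch, "liability_threshold"))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / nrep))
})

test_that("studies honour counts, missingness and the sampling cap", {
  b <- tiny_bundle()
  st <- b$studies[[1]]
  expect_equal(sum(st$phenotype == 1), 45)
  expect_equal(sum(st$phenotype == 0), 55)
  expect_equal(dim(st$geno), c(100, 400))
  cfg <- tiny_config(missing_rate = 0)
  ann <- simulate_annotation(cfg)
  arch <- simulate_effects(cfg, ann, make_gene_sets(ann, cfg))
  st0 <- simulate_study(arch, ann$snps, 10, 10, missing_rate = 0, seed = 4)
  expect_false(anyNA(st0$geno))
  # controls are scarce at high prevalence: cap must trip and be named
  cfgX <- tiny_config(prevalence = 0.95)
  annX <- simulate_annotation(cfgX)
  archX <- simulate_effects(cfgX, annX, make_gene_sets(annX, cfgX))
  expect_error(
    simulate_study(archX, annX$snps, 5, 80, seed = 4, max_batches = 1),
    class = "omniprs_error_sampling")
  expect_match(tryCatch(
    simulate_study(archX, annX$snps, 5, 80, seed = 4, max_batches = 1),
    error = conditionMessage), "cap of 1")
})

test_that("gene sets have requested sizes, overlap and deterministic membership", {
  cfg <- tiny_config(seed = 13L, set_overlap_fraction = 0)
  ann <- simulate_annotation(cfg)
  sets1 <- make_gene_sets(ann, cfg)
  sets2 <- make_gene_sets(ann, cfg)
  expect_identical(sets1, sets2)
  expect_length(sets1$core, 15)
  # overlap fraction 0: every pairwise intersection is empty
  expect_length(intersect(sets1$core, sets1$control1), 0)
  expect_length(intersect(sets1$core, sets1$control2), 0)
  expect_length(intersect(sets1$control1, sets1$control2), 0)
  expect_error(make_gene_sets(ann, tiny_config(core_set_genes = 500L)),
               class = "omniprs_error_config")
  cfg2 <- tiny_config(seed = 13L, set_overlap_fraction = 0.4)
  sets3 <- make_gene_sets(ann, cfg2)
  expect_equal(length(intersect(sets3$core, sets3$control1)), 6)  # 0.4 * 15
})

test_that("a true-beta PRS separates cases from controls increasingly with h2", {
  r2_at <- function(h2) {
    cfg <- tiny_config(seed = 303L, h2_liability = h2, n_snps = 600L,
                       cases_per_study = rep(150L, 4),
                       controls_per_study = rep(150L, 4))
    ann <- simulate_annotation(cfg)
    arch <- simulate_effects(cfg, ann, make_gene_sets(ann, cfg))
    st <- simulate_study(arch, ann$snps, 150, 150, seed = 8,
                         missing_rate = 0)
    score <- as.numeric(st$geno %*% arch$beta)
    f1 <- suppressWarnings(fit_logistic(st$phenotype, cbind(score = score)))
    f0 <- fit_logistic(st$phenotype, NULL)
    nagelkerke(f1$loglik, f0$loglik, f1$n)
  }
  r2 <- vapply(c(0, 0.1, 0.3), r2_at, numeric(1))
  expect_lt(r2[1], 0.03)           # null: essentially nothing explained
  expect_gt(r2[2], r2[1])
  expect_gt(r2[3], r2[2])
})
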