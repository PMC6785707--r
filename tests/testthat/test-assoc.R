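test_that("fit_logistic reproduces the contingency-table odds ratio and null log-likelihood", {
  # cases: 30 exposed / 20 unexposed; controls: 10 / 40 -> OR = (30*40)/(20*10) = 6
  y <- c(rep(1, 50), rep(0, 50))
  x <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  fit <- fit_logistic(y, cbind(exposure = x))
  expect_equal(unname(exp(fit$coefficients["exposure"])), 6.0, tolerance = 1e-6)
  # intercept-only log-likelihood has the closed form n*(p log p + (1-p) log(1-p))
  f0 <- fit_logistic(y, NULL)
  p <- mean(y)
  expect_equal(f0$loglik, 100 * (p * log(p) + (1 - p) * log(1 - p)),
               tolerance = 1e-8)
  expect_equal(f0$df, 1)
})

test_that("rank-deficient columns are dropped and separation is flagged, not fatal", {
  set.seed(2)
  y <- rbinom(60, 1, 0.5)
  X <- cbind(a = rnorm(60), b = rnorm(60))
  expect_warning(f <- fit_logistic(y, cbind(X, dup = X[, "a"])),
                 class = "omniprs_warning_rank_deficient")
  expect_equal(f$df, 3)
  ysep <- c(rep(0, 30), rep(1, 30))
  xsep <- c(rnorm(30, -3), rnorm(30, 3))
  expect_warning(fs <- fit_logistic(ysep, cbind(x = xsep)),
                 class = "omniprs_warning_separation")
  expect_true(fs$flagged)
  expect_true(all(is.finite(fs$coefficients)))
})

test_that("likelihood-ratio test matches the chi-square distribution oracle", {
  f <- structure(list(loglik = -10, df = 3, n = 50), class = "fit_result")
  b <- structure(list(loglik = -10, df = 2, n = 50), class = "fit_result")
  t0 <- lrt(f, b)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  f2 <- structure(list(loglik = -10 + qchisq(0.95, 1) / 2, df = 3, n = 50),
                  class = "fit_result")
  t1 <- lrt(f2, b)
  expect_equal(t1$statistic, 3.841459, tolerance = 1e-6)
  expect_equal(t1$p_value, 0.05, tolerance = 1e-9)
  expect_error(lrt(b, b), class = "omniprs_error_nesting")
  bad <- structure(list(loglik = -5, df = 2, n = 50), class = "fit_result")
  expect_error(lrt(f, bad, df = 1), class = "omniprs_error_convergence")
})

test_that("nagelkerke matches independent arithmetic and is monotone in fit", {
  expect_equal(nagelkerke(-4, -4, 20), 0)
  expect_equal(nagelkerke(0, -30, 50), 1)   # perfect prediction saturates at 1
  # 8-sample fixture: y has 3 cases, ll_null = 3 log(3/8) + 5 log(5/8)
  expect_equal(nagelkerke(-3.2, 3 * log(3 / 8) + 5 * log(5 / 8), 8),
               0.5551807126, tolerance = 1e-9)
  lls <- seq(-5.2, -3.2, by = 0.5)
  r2s <- vapply(lls, nagelkerke, 0, ll_null = -5.2925059, n = 8)
  expect_true(all(diff(r2s) > 0))
  expect_error(nagelkerke(-1, -2, 0), class = "omniprs_error_empty")
})

test_that("null GWAS p-values are uniform and missing dosages are dropped per SNP", {
  cfg <- tiny_config(seed = 41L, h2_liability = 0, study_drift_f = 0,
                     n_snps = 600L)
  b <- simulate_cohorts(cfg)
  pool <- pool_studies(b$studies)
  stats <- gwas(pool)
  expect_gt(suppressWarnings(ks.test(stats$p[!stats$flagged], "punif"))$p.value,
            0.01)
  bins <- decile_bins(stats[!stats$flagged, ])
  expect_equal(sum(bins), 1)
  expect_true(all(abs(bins - 0.1) < 5 * sqrt(0.1 * 0.9 / nrow(stats))))
  # per-SNP sample drop: n reflects missingness of that SNP alone
  expect_equal(stats$n, unname(colSums(!is.na(pool$geno[!is.na(pool$y), ]))))
})

test_that("GWAS recovers effect signs and is equivariant under allele relabeling", {
  cfg <- tiny_config(seed = 43L, h2_liability = 0.5, n_snps = 200L,
                     cases_per_study = rep(120L, 4),
                     controls_per_study = rep(120L, 4))
  b <- simulate_cohorts(cfg)
  pool <- pool_studies(b$studies)
  stats <- gwas(pool)
  big <- order(-abs(b$arch$beta))[1:15]  # strongest true liability effects
  agree <- sign(stats$lnor[big]) == sign(b$arch$beta[big])
  expect_gt(mean(agree), 0.7)
  # relabel A1/A2 with dosage complement at one SNP: lnor negates, p unchanged
  pool2 <- pool
  pool2$geno[, 5] <- 2 - pool2$geno[, 5]
  tmp <- pool2$snps$a1[5]
  pool2$snps$a1[5] <- pool2$snps$a2[5]
  pool2$snps$a2[5] <- tmp
  stats2 <- gwas(pool2)
  expect_equal(stats2$lnor[5], -stats$lnor[5], tolerance = 1e-6)
  expect_equal(stats2$p[5], stats$p[5], tolerance = 1e-6)
})

test_that("orient_risk flips negative effects, keeps ties, and is idempotent", {
  st <- data.frame(snp_id = c("a", "b", "c"), a1 = c("A", "C", "G"),
                   a2 = c("T", "G", "A"), lnor = c(-0.2, 0, 0.3),
                   se = 0.1, p = 0.5, n = 10L, flagged = FALSE,
                   stringsAsFactors = FALSE)
  o <- orient_risk(st)
  expect_equal(o$lnor, c(0.2, 0, 0.3))
  expect_equal(o$a1, c("T", "C", "G"))  # flipped; tie keeps A1
  expect_equal(o$a2, c("A", "G", "A"))
  expect_identical(orient_risk(o), o)
  expect_true(all(o$lnor >= 0))
})
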