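loo_records <- function(p, direction = 1, n_cases = 500L, n_controls = 500L,
                        r2 = NULL, flagged = FALSE) {
  data.frame(held_out_study = sprintf("s%d", seq_along(p)), p_value = p,
             direction = rep_len(direction, length(p)),
             n_cases = rep_len(n_cases, length(p)),
             n_controls = rep_len(n_controls, length(p)),
             nested_r2 = if (is.null(r2)) runif(length(p), 0, 0.01) else r2,
             flagged = rep_len(flagged, length(p)), stringsAsFactors = FALSE)
}

test_that("stouffer reproduces closed forms and the hand-computed two-study case", {
  one <- stouffer(loo_records(0.02, direction = -1))
  expect_equal(one$p_meta, 0.02, tolerance = 1e-12)
  expect_equal(one$z_meta, -qnorm(1 - 0.01), tolerance = 1e-12)
  # k identical studies with equal n: z_meta = z0 * sqrt(k)
  k <- 5; p0 <- 0.04
  same <- stouffer(loo_records(rep(p0, k)))
  expect_equal(same$z_meta, qnorm(1 - p0 / 2) * sqrt(k), tolerance = 1e-12)
  # two studies, hand-evaluated weighted formula:
  # z = (sqrt(1000)*2.5758293 - sqrt(500)*1.2815516) / sqrt(1500)
  two <- stouffer(loo_records(c(0.01, 0.20), direction = c(1, -1),
                              n_cases = c(500L, 250L),
                              n_controls = c(500L, 250L)))
  expect_equal(two$z_meta, 1.3632517, tolerance = 1e-6)
})

test_that("stouffer is order-invariant, sign-equivariant, and excludes flagged records", {
  set.seed(3)
  rec <- loo_records(runif(8, 0.001, 0.9), direction = sample(c(-1, 1), 8, TRUE),
                     n_cases = sample(100:900, 8))
  m1 <- stouffer(rec)
  m2 <- stouffer(rec[sample(8), ])
  expect_equal(m1$z_meta, m2$z_meta)
  rec_neg <- rec; rec_neg$direction <- -rec$direction
  m3 <- stouffer(rec_neg)
  expect_equal(m3$z_meta, -m1$z_meta)
  expect_equal(m3$p_meta, m1$p_meta)
  rec$flagged[1:2] <- TRUE
  m4 <- stouffer(rec)
  expect_equal(m4$n_excluded, 2)
  expect_equal(m4$n_studies, 6)
  expect_equal(m4$z_meta, stouffer(rec[-(1:2), ])$z_meta)
  expect_error(stouffer(rec[0, ]), class = "omniprs_error_empty")
  expect_warning(stouffer(loo_records(c(0, 0.5))), class = "omniprs_warning_p_clamp")
  # effective-n weighting differs once case/control ratios are unbalanced
  unb <- loo_records(c(0.01, 0.3), n_cases = c(900L, 100L),
                     n_controls = c(100L, 900L))
  expect_equal(stouffer(unb, weight = "effective")$z_meta,
               sum(sqrt(c(360, 360)) * qnorm(1 - c(0.01, 0.3) / 2)) /
                 sqrt(720), tolerance = 1e-12)
})

test_that("R2 summaries follow order statistics with interpolated quartiles", {
  one <- summarize_r2(loo_records(0.5, r2 = 0.007))
  expect_equal(one$r2_median, 0.007)
  expect_equal(one$r2_iqr, 0)
  expect_equal(one$r2_range, c(0.007, 0.007))
  four <- summarize_r2(loo_records(rep(0.5, 4), r2 = c(1, 2, 3, 4)))
  expect_equal(four$r2_median, 2.5)
  # 39 simulated records vs an independent sort-and-index oracle
  set.seed(9)
  v <- rexp(39, 100)
  s <- summarize_r2(loo_records(rep(0.5, 39), r2 = v))
  sv <- sort(v)
  expect_equal(s$r2_median, sv[20])
  expect_equal(s$r2_range, c(sv[1], sv[39]))
  # type-7 interpolation: h = (n-1)p + 1
  q25 <- sv[10] + 0.5 * (sv[11] - sv[10])
  q75 <- sv[29] + 0.5 * (sv[30] - sv[29])
  expect_equal(s$r2_iqr, q75 - q25)
})

test_that("decile bins partition p-values and detect enrichment", {
  st <- data.frame(snp_id = sprintf("s%d", 1:5), p = rep(0.05, 5))
  bins <- decile_bins(st)
  expect_equal(bins, c(1, rep(0, 9)))
  expect_error(decile_bins(st, snp_set = "absent"), class = "omniprs_error_empty")
  set.seed(1)
  stu <- data.frame(snp_id = sprintf("s%d", 1:5000), p = runif(5000))
  b2 <- decile_bins(stu)
  expect_equal(sum(b2), 1)
  expect_true(all(abs(b2 - 0.1) < 0.03))
  # boundary values land in the lower-edge-closed bin; p = 1 stays in bin 10
  b3 <- decile_bins(data.frame(snp_id = c("a", "b", "c"), p = c(0.1, 0.9999, 1)))
  expect_equal(b3[2], 1 / 3)
  expect_equal(b3[10], 2 / 3)
})

test_that("expected_share reproduces the proportional-allocation worked example", {
  # genome-wide R2 0.24 over 3,848,785 SNPs allocated to gene-set-sized subsets
  expect_equal(round(100 * expected_share(0.24, 3848785, 4986), 2), 0.03)
  expect_equal(round(100 * expected_share(0.24, 3848785, 8807), 3), 0.055)
  expect_equal(expected_share(0.24, 3848785, 0), 0)
  # linear in the set size
  expect_equal(expected_share(0.24, 1000, 300),
               3 * expected_share(0.24, 1000, 100))
  expect_error(expected_share(0.24, 0, 10), class = "omniprs_error_config")
})
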