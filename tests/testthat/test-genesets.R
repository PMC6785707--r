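test_that("genic classification honours strand-aware margins and boundaries", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "1",
                      start = c(50000, 200000), end = c(60000, 210000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  snps <- data.frame(
    snp_id = sprintf("x%d", 1:8), chrom = "1",
    pos = c(55000,        # inside gene body
            45000,        # exactly 5 kb 5' of + gene start: genic (inclusive)
            44999,        # 1 bp beyond the upstream margin
            61000,        # exactly 1 kb 3' of + gene end
            61001,        # beyond the downstream margin
            215000,       # 5 kb above a - gene end: upstream side, genic
            199001,       # 999 bp below - gene start: downstream side, genic
            194999),      # 5001 bp below - gene start: non-genic
    stringsAsFactors = FALSE)
  cls <- classify_genic(snps, genes)
  expect_equal(unname(cls$genic),
               c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  # strand-unaware option treats the - gene like a + gene
  cls2 <- classify_genic(snps, genes, strand_aware = FALSE)
  expect_false(unname(cls2$genic[6]))  # 215000 > end + 1 kb
})

test_that("classification matches a brute-force interval oracle and partitions SNPs", {
  set.seed(21)
  genes <- data.frame(gene_id = sprintf("g%d", 1:3), chrom = "1",
                      start = c(10000, 40000, 80000),
                      end = c(15000, 47000, 85000),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = sprintf("x%02d", 1:20), chrom = "1",
                     pos = sort(sample.int(1e5, 20)), stringsAsFactors = FALSE)
  m <- genic_margins(5000, 1000)
  cls <- classify_genic(snps, genes, m)
  oracle <- vapply(snps$pos, function(p) {
    any(vapply(seq_len(3), function(g) {
      if (genes$strand[g] == "+")
        p >= genes$start[g] - 5000 && p <= genes$end[g] + 1000
      else
        p >= genes$start[g] - 1000 && p <= genes$end[g] + 5000
    }, logical(1)))
  }, logical(1))
  expect_equal(unname(cls$genic), oracle)
  expect_equal(sum(cls$genic) + sum(!cls$genic), 20)  # exact partition
})

test_that("gene-set to SNP-set mapping deduplicates and warns on unknown genes", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "1",
                      start = c(1000, 4000), end = c(3000, 6000),
                      strand = "+", stringsAsFactors = FALSE)
  # gene A covers 3 SNPs, gene B covers 2, one shared in overlapping margins
  snps <- data.frame(snp_id = sprintf("x%d", 1:4), chrom = "1",
                     pos = c(1500, 2500, 3500, 5000), stringsAsFactors = FALSE)
  cls <- classify_genic(snps, genes, genic_margins(1000, 1000))
  expect_length(cls$assignments$A, 3)
  expect_length(cls$assignments$B, 2)
  expect_setequal(snps_for_gene_set(c("A", "B"), cls), snps$snp_id)  # |union| = 4
  expect_length(snps_for_gene_set(character(0), cls), 0)
  expect_warning(out <- snps_for_gene_set(c("A", "GHOST"), cls),
                 class = "omniprs_warning_unknown_gene")
  expect_setequal(out, cls$assignments$A)
})

test_that("overlap statistics cover the intersection lattice and sum to 100%", {
  o <- overlap_stats(list(s1 = c("a", "b", "c"), s2 = c("b", "c", "d")))
  expect_equal(o$count[o$region == "s1&s2"], 2)
  expect_equal(o$pct[o$region == "s1&s2"], 50)   # 2 of the 4-gene union
  expect_equal(sum(o$pct), 100)
  disj <- overlap_stats(list(a = c("x", "y"), b = c("z")))
  expect_equal(disj$count[disj$region == "a&b"], 0)
  ident <- overlap_stats(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(ident$pct[ident$region == "a&b"], 100)
  expect_equal(sum(overlap_stats(list(a = letters[1:5], b = letters[3:9],
                                      c = letters[6:12]))$pct), 100)
  expect_error(overlap_stats(list(only = "a")), class = "omniprs_error_config")
})

test_that("random sets are deterministic, truncated with warning, pool-respecting", {
  pool <- sprintf("p%03d", 1:30)
  s1 <- draw_random_sets(pool, n_sets = 4, set_size = 10, seed = 9)
  s2 <- draw_random_sets(pool, n_sets = 4, set_size = 10, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(lengths(s1) == 10))
  expect_true(all(unlist(s1) %in% pool))
  expect_true(all(vapply(s1, anyDuplicated, 0L) == 0))  # without replacement
  # pool of exactly set_size: every set is the pool
  sp <- draw_random_sets(pool, n_sets = 3, set_size = 30, seed = 1)
  expect_true(all(vapply(sp, setequal, TRUE, pool)))
  expect_warning(draw_random_sets(pool, 1, 50, seed = 1),
                 class = "omniprs_warning_truncated_set")
  expect_error(draw_random_sets(character(0), 1, 5),
               class = "omniprs_error_empty_pool")
})

test_that("SNP sets round-trip through one-ID-per-line text", {
  f <- withr::local_tempfile()
  ids <- sprintf("rs%04d", c(12, 7, 901))
  write_snp_set(ids, f)
  expect_identical(read_snp_set(f), ids)
})

test_that("genic and non-genic random pools stay disjoint through the pipeline", {
  b <- tiny_bundle()
  cls <- classify_genic(b$annotation$snps, b$annotation$genes, b$cfg$margins)
  pool <- pool_studies(b$studies)
  pruned <- ld_prune(pool$geno, prune_params(r2_max = 0.01))
  genic_pool <- intersect(pruned, names(cls$genic)[cls$genic])
  nongenic_pool <- setdiff(pruned, names(cls$genic)[cls$genic])
  expect_length(intersect(genic_pool, nongenic_pool), 0)
  gs <- draw_random_sets(genic_pool, 3, 25, seed = 2)
  ns <- draw_random_sets(nongenic_pool, 3, 25, seed = 2)
  expect_true(all(cls$genic[unlist(gs)]))
  expect_false(any(cls$genic[unlist(ns)]))
})
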