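test_that("effective allele number follows 1/sum(p^2)", {
  expect_equal(effective_alleles(c(0.5, 0.5)), 2)
  expect_equal(effective_alleles(1), 1)
  expect_equal(effective_alleles(c(0.7, 0.2, 0.1)), 1 / 0.54, tolerance = 1e-4)
  expect_error(effective_alleles(c(0.5, 0.4)), "sum to 1")
  # n_e <= n_a with equality only when equifrequent
  for (k in 2:5) {
    p <- rep(1 / k, k)
    expect_equal(effective_alleles(p), k)
  }
  for (k in 3:5) {
    p2 <- c(0.5, rep(0.5 / (k - 1), k - 1))
    expect_lt(effective_alleles(p2), k)
  }
})

test_that("heterozygosities match hand computations and symmetry", {
  g <- make_g(rbind(c(10, 12), c(10, 10)))
  hh <- heterozygosities(g, 1)
  expect_equal(hh[["Ho"]], 0.5)
  expect_equal(hh[["He"]], (4 / 3) * (1 - 0.625))
  # monomorphic
  g2 <- make_g(rbind(c(7, 7), c(7, 7)))
  expect_equal(unname(heterozygosities(g2, 1)), c(0, 0))
  # invariance under allele relabeling
  g3 <- make_g(rbind(c(10, 12), c(12, 14), c(10, 10), c(14, 14)))
  g4 <- make_g(rbind(c(30, 20), c(20, 5), c(30, 30), c(5, 5)))
  expect_equal(heterozygosities(g3, 1)[["He"]], heterozygosities(g4, 1)[["He"]])
})

test_that("Hardy-Weinberg G-test behaves at both extremes", {
  # exact HWE proportions 25/50/25: G ~ 0, p ~ 1
  a1 <- c(rep(10L, 25), rep(10L, 50), rep(12L, 25))
  a2 <- c(rep(10L, 25), rep(12L, 50), rep(12L, 25))
  g <- make_g(cbind(a1, a2))
  res <- hwe_gtest(g, 1, n_perm = 300, seed = 7)
  expect_lt(res$G, 1e-8)
  expect_gt(res$p, 0.9)
  # all heterozygotes: strong departure
  g2 <- make_g(cbind(rep(10L, 50), rep(12L, 50)))
  res2 <- hwe_gtest(g2, 1, n_perm = 1000, seed = 8)
  expect_lt(res2$p, 0.01)
  expect_error(hwe_gtest(g, 1, n_perm = 50), "at least 100")
})

test_that("HWE permutation p-values are near-uniform under the null", {
  set.seed(9)
  n_rep <- 40
  rej <- 0L
  for (r in seq_len(n_rep)) {
    g <- simulate_dataset(n_ind = 20, n_loci_sim = 1, group_sizes = c(a = 20L),
                          missing_rate = 0, seed = 900 + r)
    if (length(allele_frequencies(g, 1)) < 2) next
    p <- hwe_gtest(g, 1, n_perm = 200)$p
    expect_gte(p, 1 / 201)
    if (p <= 0.05) rej <- rej + 1L
  }
  expect_lte(rej, ceiling(n_rep * (0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))))
})

test_that("genotypic disequilibrium G-test detects self-association only", {
  set.seed(10)
  g <- simulate_dataset(n_ind = 25, n_loci_sim = 2, group_sizes = c(a = 25L),
                        missing_rate = 0, seed = 11)
  # a locus paired with itself: perfect association
  g_self <- genotype_matrix(g$a1[, c(1, 1)], g$a2[, c(1, 1)], g$groups,
                            list(locus("A"), locus("B")))
  expect_lt(ld_gtest(g_self, "A", "B", n_perm = 300, seed = 12)$p, 0.02)
  # independently simulated loci: moderate p most of the time
  rej <- 0L
  for (r in 1:20) {
    gi <- simulate_dataset(n_ind = 20, n_loci_sim = 2, group_sizes = c(a = 20L),
                           missing_rate = 0, seed = 1200 + r)
    p <- tryCatch(ld_gtest(gi, 1, 2, n_perm = 150)$p, error = function(e) NA)
    if (!is.na(p) && p <= 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 5)
})

test_that("F_IS hits its analytic limits and sign contracts", {
  # all homozygotes, two equifrequent alleles -> F_IS ~ 1
  a <- rep(c(10L, 14L), each = 20)
  g <- make_g(cbind(a, a), cbind(a, a))
  f <- fis(g, n_rand = 100, n_boot = 100, seed = 13)
  expect_gt(min(f$per_locus$fis), 0.99)
  # all heterozygotes -> strongly negative
  g2 <- make_g(cbind(rep(10L, 40), rep(12L, 40)),
               cbind(rep(10L, 40), rep(12L, 40)))
  f2 <- fis(g2, n_rand = 100, n_boot = 100, seed = 14)
  expect_lt(max(f2$per_locus$fis), 0)
  # large balanced HWE sample -> near 0
  a1 <- c(rep(10L, 100), rep(10L, 200), rep(12L, 100))
  a2 <- c(rep(10L, 100), rep(12L, 200), rep(12L, 100))
  g3 <- make_g(cbind(a1, a2))
  f3 <- fis(g3, n_rand = 100, n_boot = 100, seed = 15)
  expect_lt(abs(f3$per_locus$fis[1]), 0.02)
  # weighted mean lies between per-locus extremes; bootstrap CI ordered
  set.seed(16)
  g4 <- simulate_dataset(n_ind = 20, n_loci_sim = 5, group_sizes = c(a = 20L),
                         missing_rate = 0, seed = 17)
  f4 <- suppressWarnings(fis(g4, n_rand = 100, n_boot = 200))
  ok <- !is.na(f4$per_locus$fis)
  expect_gte(f4$weighted_mean, min(f4$per_locus$fis[ok]) - 1e-9)
  expect_lte(f4$weighted_mean, max(f4$per_locus$fis[ok]) + 1e-9)
  expect_lte(f4$ci[1], f4$ci[2])
})

test_that("sequential Bonferroni implements the Holm ladder", {
  expect_equal(sequential_bonferroni(c(0.01, 0.02, 0.04), 0.05),
               c(TRUE, TRUE, TRUE))
  expect_equal(sequential_bonferroni(c(0.04, 0.5, 0.9), 0.05),
               c(FALSE, FALSE, FALSE))
  expect_equal(sequential_bonferroni(0.05, 0.05), TRUE)  # boundary inclusive
  expect_equal(sequential_bonferroni(numeric(0), 0.05), logical(0))
  # rejects a superset of classical Bonferroni
  set.seed(18)
  for (r in 1:25) {
    p <- stats::runif(8)^2
    holm <- sequential_bonferroni(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(holm[bonf]))
  }
  # stops at the first failure even though later p sit under their own
  # (larger) thresholds: 0.02 > 0.05/3 blocks 0.03 <= 0.05/2 and 0.04 <= 0.05
  expect_equal(sequential_bonferroni(c(0.04, 0.02, 0.03), 0.05),
               c(FALSE, FALSE, FALSE))
})

test_that("locus summary table carries the standard columns", {
  set.seed(19)
  g <- simulate_dataset(n_ind = 15, n_loci_sim = 3, group_sizes = c(a = 15L),
                        seed = 20)
  s <- locus_summary(g, n_perm = 150, n_rand = 50)
  expect_equal(names(s), c("locus", "N", "n_a", "n_e", "Ho", "He", "Fis", "p_HWE"))
  expect_true(all(s$n_e <= s$n_a + 1e-9))
  expect_true(all(s$Ho >= 0 & s$Ho <= 1))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(s, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), 3)
})
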