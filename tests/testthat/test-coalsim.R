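test_that("coalescent waiting times match Kingman expectations", {
  set.seed(41)
  t2 <- replicate(8000, root_height(simulate_genealogy(2, constant_demography(2))))
  expect_equal(mean(t2), 2, tolerance = 0.08)          # E[T2] = theta
  tm <- replicate(2500, root_height(simulate_genealogy(10, constant_demography(2))))
  expect_equal(mean(tm), 2 * 2 * (1 - 1 / 10), tolerance = 0.1)
})

test_that("node times increase root-ward and seeds reproduce bit-identically", {
  tr <- simulate_genealogy(12, constant_demography(1), seed = 42)
  for (v in seq_along(tr$parent)) {
    if (tr$parent[v] != 0L) expect_gt(tr$time[tr$parent[v]], tr$time[v] - 1e-15)
  }
  tr2 <- simulate_genealogy(12, constant_demography(1), seed = 42)
  expect_identical(tr, tr2)
  g1 <- simulate_dataset(n_ind = 10, n_loci_sim = 2, group_sizes = c(a = 10L),
                         seed = 43)
  g2 <- simulate_dataset(n_ind = 10, n_loci_sim = 2, group_sizes = c(a = 10L),
                         seed = 43)
  expect_identical(g1, g2)
})

test_that("exponential-growth times follow the closed-form inverse CDF", {
  set.seed(44)
  th0 <- 1.5; gr <- 2
  draws <- replicate(10000,
    root_height(simulate_genealogy(2, exponential_demography(th0, gr))))
  # for n = 2 the cumulative hazard is (exp(g t) - 1)/(theta0 g), so
  # T = log(1 + E theta0 g)/g with E ~ Exp(1)
  cdf <- function(t) 1 - exp(-(exp(gr * t) - 1) / (th0 * gr))
  ks <- stats::ks.test(draws, cdf)
  expect_gt(ks$p.value, 0.01)
})

test_that("piecewise demographies integrate and invert exactly", {
  dem <- piecewise_demography(c(0.4, 1.1), c(2, 0.5, 4))
  expect_equal(theta_at(dem, c(0, 0.4, 1.2)), c(2, 0.5, 4))
  expect_equal(msatdemog:::intensity_integral(dem, 0.2, 1.3),
               0.2 / 2 + 0.7 / 0.5 + 0.2 / 4)
  # waiting-time inversion agrees with the integral it inverts
  set.seed(45)
  for (r in 1:20) {
    e <- stats::rexp(1); t0 <- stats::runif(1, 0, 1.5); k <- sample(2:6, 1)
    dt <- msatdemog:::coalescent_waiting_time(dem, t0, k, e)
    reached <- k * (k - 1) / 2 * msatdemog:::intensity_integral(dem, t0, t0 + dt)
    expect_equal(reached, e, tolerance = 1e-10)
  }
  expect_error(piecewise_demography(c(1, 0.5), c(1, 1, 1)), "increasing")
  expect_error(piecewise_demography(1, c(1, -2)), "positive")
})

test_that("microsatellite evolution reaches stationarity on long branches", {
  set.seed(46)
  mo <- mutation_model_by_name("EU1", i_min = 1, i_max = 8)
  Q <- build_rate_matrix(mo)
  # star-like manual tree with very long branches
  ch <- matrix(NA_integer_, 5, 2); ch[4, ] <- c(1L, 2L); ch[5, ] <- c(4L, 3L)
  tr <- make_tree(3, c(4L, 4L, 5L, 5L, 0L), ch, c(0, 0, 0, 500, 1000))
  tips <- replicate(700, evolve_microsatellite(tr, mo, Q = Q))
  pi <- stationary_distribution(Q)
  obs <- table(factor(tips, levels = 1:8))
  chi <- stats::chisq.test(obs, p = pi)
  expect_gt(chi$p.value, 0.01)
  # zero-length branches copy the root state
  tr0 <- make_tree(3, c(4L, 4L, 5L, 5L, 0L), ch, c(0, 0, 0, 0, 0))
  tt <- evolve_microsatellite(tr0, mo, Q = Q, seed = 47)
  expect_length(unique(tt), 1L)
})

test_that("pairwise squared size difference grows like branch length", {
  set.seed(48)
  mo <- mutation_model_by_name("EU1")  # step variance 1, mean rate 1
  Q <- build_rate_matrix(mo)
  h <- 0.05
  ch <- matrix(NA_integer_, 3, 2); ch[3, ] <- c(1L, 2L)
  tr <- make_tree(2, c(3L, 3L, 0L), ch, c(0, 0, h))
  d2 <- replicate(4000, {
    tt <- evolve_microsatellite(tr, mo, Q = Q)
    (tt[1] - tt[2])^2
  })
  expect_equal(mean(d2), 2 * h, tolerance = 0.25)
})

test_that("the synthetic dataset matches the emulated study shape", {
  g <- simulate_dataset(seed = 49)
  expect_equal(n_individuals(g), 85L)
  expect_equal(n_loci(g), 10L)
  expect_length(unique(g$groups), 6L)
  ks <- vapply(seq_len(n_loci(g)), function(j) {
    length(unique(msatdemog:::gene_copies(g, j)))
  }, 0L)
  expect_true(all(ks >= 2 & ks <= 20))
  expect_gte(mean(ks >= 3 & ks <= 14), 0.7)
  rng <- range(c(g$a1, g$a2), na.rm = TRUE)
  expect_gte(rng[1], 1); expect_lte(rng[2], 35)
  # missing injection off
  g0 <- simulate_dataset(n_ind = 10, n_loci_sim = 2, group_sizes = c(a = 10L),
                         missing_rate = 0, seed = 50)
  expect_false(anyNA(g0$a1))
})

test_that("structured simulation needs valid settings and mixes at high M", {
  expect_error(simulate_dataset(group_sizes = c(a = 5L, b = 5L), migration = 0,
                                n_loci_sim = 1),
               "migration")
  expect_error(simulate_dataset(group_sizes = c(a = 5L, b = 5L),
                                dem = exponential_demography(1, 1),
                                n_loci_sim = 1),
               "constant demography")
})

test_that("genealogies export to ape and Newick", {
  tr <- simulate_genealogy(6, constant_demography(1), seed = 51)
  phy <- genealogy_to_phylo(tr)
  expect_s3_class(phy, "phylo")
  expect_equal(ape::Ntip(phy), 6)
  expect_equal(max(ape::node.depth.edgelength(phy)), root_height(tr),
               tolerance = 1e-12)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_genealogy_newick(list(tr, tr), nwk)
  back <- ape::read.tree(nwk)
  expect_length(back, 2)
})
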