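test_that("coalescent log density matches closed forms and quadrature", {
  ch <- matrix(NA_integer_, 3, 2); ch[3, ] <- c(1L, 2L)
  tr <- make_tree(2, c(3L, 3L, 0L), ch, c(0, 0, 0.7))
  expect_equal(coalescent_loglik(tr, constant_demography(3)),
               -log(3) - 0.7 / 3)
  # piecewise with equal segments collapses to the constant value
  dem_flat <- piecewise_demography(c(0.2, 0.5), c(3, 3, 3))
  expect_equal(coalescent_loglik(tr, dem_flat), -log(3) - 0.7 / 3)
  # arbitrary piecewise case against numeric quadrature
  set.seed(52)
  tr2 <- simulate_genealogy(9, constant_demography(1))
  dem <- piecewise_demography(c(0.3, 0.9), c(2, 0.4, 5))
  ev <- sort(tr2$time[10:17]); k <- 9:2; lo <- c(0, ev[-8])
  I <- vapply(seq_along(ev), function(i) {
    stats::integrate(function(t) 1 / theta_at(dem, t), lo[i], ev[i],
                     rel.tol = 1e-11)$value
  }, 0)
  oracle <- -sum(k * (k - 1) / 2 * I) - sum(log(theta_at(dem, ev)))
  expect_equal(coalescent_loglik(tr2, dem), oracle, tolerance = 1e-8)
  # exponential demography against quadrature too
  dem_e <- exponential_demography(2, 1.3)
  I_e <- vapply(seq_along(ev), function(i) {
    stats::integrate(function(t) 1 / theta_at(dem_e, t), lo[i], ev[i],
                     rel.tol = 1e-11)$value
  }, 0)
  oracle_e <- -sum(k * (k - 1) / 2 * I_e) - sum(log(theta_at(dem_e, ev)))
  expect_equal(coalescent_loglik(tr2, dem_e), oracle_e, tolerance = 1e-8)
})

test_that("pruning likelihood agrees with stationarity and exhaustion", {
  mo <- mutation_model_by_name("EU2", i_min = 1, i_max = 8)
  Q <- build_rate_matrix(mo)
  pi <- stationary_distribution(Q)
  tr <- tree3(0.3, 0.8)
  # a single observed tip (others missing) carries exactly ln pi_i
  for (i in c(1L, 4L, 8L)) {
    expect_equal(pruning_loglik(c(i, NA, NA), tr, Q), log(pi[[as.character(i)]]),
                 tolerance = 1e-10)
  }
  # all tips missing: likelihood 1
  expect_equal(pruning_loglik(c(NA, NA, NA), tr, Q), 0)
  # tips outside the lattice are rejected
  expect_error(pruning_loglik(c(9L, 1L, 1L), tr, Q), "outside the model lattice")
  # rate modifiers stretch branch lengths
  expect_equal(pruning_loglik(c(2L, 5L, 7L), tr, Q, rate_modifier = 2),
               pruning_loglik(c(2L, 5L, 7L),
                              make_tree(3, tr$parent, tr$children, tr$time * 2),
                              Q),
               tolerance = 1e-10)
})

test_that("3-leaf pruning equals the exhaustive sum for every model", {
  tr <- tree3(0.35, 1.1)
  tips <- c(3L, 5L, 4L)
  for (nm in msat_model_names()) {
    Q <- build_rate_matrix(mutation_model_by_name(nm, i_min = 1, i_max = 8))
    expect_equal(pruning_loglik(tips, tr, Q), brute_force_3leaf(tips, tr, Q),
                 tolerance = 1e-9, label = nm)
  }
})

test_that("marginal-likelihood estimators recover a constant likelihood", {
  lnl <- rep(-3.7, 500)
  expect_equal(estimate_lnml(lnl, "HARMONIC_MEAN")$lnml, -3.7)
  ss <- estimate_lnml(list(traces = rep(list(lnl), 5),
                           betas = c(0, 0.1, 0.3, 0.5, 0.8, 1)),
                      "STEPPING_STONE")
  expect_equal(ss$lnml, -3.7, tolerance = 1e-12)
  expect_error(estimate_lnml(list(traces = rep(list(lnl), 3),
                                  betas = c(0, 0.5, 0.9, 1)), "STEPPING_STONE"),
               "at least 4")
  expect_error(estimate_lnml(list(traces = rep(list(lnl), 4),
                                  betas = c(0, 0.5, 0.9, 0.95, 0.99)),
                             "STEPPING_STONE"),
               "betas")
})

test_that("stepping stone beats the harmonic mean on a conjugate toy", {
  # exponential likelihood L(x) = exp(-s x), one-on-x prior on [a, b]:
  # everything is available by quadrature, and power posteriors can be
  # sampled directly by inverse-CDF
  a <- 0.1; b <- 20; s <- 3
  lik_log <- function(x) -s * x
  z_quad <- stats::integrate(function(x) exp(-s * x) / (x * log(b / a)), a, b,
                             rel.tol = 1e-12)$value
  lnml_true <- log(z_quad)
  sample_power <- function(beta, n) {
    # density prop to exp(-beta s x)/x on [a, b]; sample by grid inversion
    xg <- exp(seq(log(a), log(b), length.out = 4000))
    w <- exp(-beta * s * xg)           # density wrt log-x measure
    cw <- cumsum(w); cw <- cw / cw[length(cw)]
    xg[findInterval(stats::runif(n), cw) + 1L]
  }
  set.seed(53)
  betas <- (seq(0, 8) / 8)^(1 / 0.3)
  reps <- 20
  ss_est <- hm_est <- numeric(reps)
  for (r in seq_len(reps)) {
    traces <- lapply(betas[1:8], function(bb) lik_log(sample_power(bb, 400)))
    ss_est[r] <- estimate_lnml(list(traces = traces, betas = betas),
                               "STEPPING_STONE")$lnml
    hm_est[r] <- estimate_lnml(lik_log(sample_power(1, 3200)),
                               "HARMONIC_MEAN")$lnml
  }
  expect_lt(abs(mean(ss_est) - lnml_true), 0.1)
  expect_lt(stats::sd(ss_est), stats::sd(hm_est))
})

test_that("model ranking and decisiveness labels follow ln BF", {
  cmp <- compare_models(c(A = -10, B = -14))
  expect_equal(cmp$lnBF, c(0, 4))
  expect_equal(cmp$decisive, c(FALSE, FALSE))
  cmp2 <- compare_models(c(A = -16, B = -10))
  expect_equal(cmp2$model, c("B", "A"))
  expect_equal(cmp2$lnBF, c(0, 6))
  expect_true(cmp2$decisive[2])
  # invariant to adding a constant
  cmp3 <- compare_models(c(A = -16, B = -10) + 123.4)
  expect_equal(cmp3$lnBF, cmp2$lnBF)
  expect_equal(compare_models(c(A = -3, B = -3))$lnBF, c(0, 0))
  expect_error(compare_models(c(A = -1)), "two models")
})

test_that("HPD intervals are shortest contiguous covers", {
  expect_equal(hpd_interval(rep(2.5, 50)), c(2.5, 2.5))
  set.seed(54)
  u <- stats::runif(20000)
  h <- hpd_interval(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.02)
  # skewed sample: HPD shorter than the central interval
  x <- stats::rexp(20000)
  h2 <- hpd_interval(x, 0.9)
  ci <- stats::quantile(x, c(0.05, 0.95))
  expect_lt(h2[2] - h2[1], ci[2] - ci[1])
  expect_equal(h2[1], 0, tolerance = 0.01)
})

test_that("posterior summaries respect their contracts", {
  set.seed(55)
  g <- simulate_dataset(n_ind = 3, n_loci_sim = 2, group_sizes = c(a = 3L),
                        model = mutation_model_by_name("EU1", i_min = 5, i_max = 20),
                        missing_rate = 0, seed = 56)
  post <- run_mcmc(g, mutation_model_by_name("EU1", i_min = 5, i_max = 20),
                   dem_kind = "SKYLINE", n_iter = 600, burnin = 0.1,
                   seed = 57, ess_warn = 0)
  expect_s3_class(post, "skyline_posterior")
  expect_true(all(c("lnL", "psi", "phi", "theta0", "TCOAL") %in%
                    names(post$samples)))
  sm <- summarize_posterior(post)
  expect_true(all(sm$skyline$lower <= sm$skyline$median + 1e-12))
  expect_true(all(sm$skyline$median <= sm$skyline$upper + 1e-12))
  expect_equal(sum(sm$psi_posterior), 1, tolerance = 1e-12)
  expect_warning(summarize_posterior(post, grid = c(0, 1e6)), "truncated")
  # trace file round trip
  tsv <- withr::local_tempfile(fileext = ".log")
  write_trace(post, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$lnL, post$samples$lnL)
  # the T_COAL summary is the mean of per-sample tallest root heights
  expect_equal(sm$tcoal[["mean"]], mean(post$samples$TCOAL))
  expect_error(run_mcmc(g, mutation_model_by_name("EU1", i_min = 5, i_max = 20),
                        n_iter = 5), "chain settings")
})

test_that("rate modifiers scale with observed allele counts, mean one", {
  set.seed(58)
  g <- simulate_dataset(n_ind = 8, n_loci_sim = 3, group_sizes = c(a = 8L),
                        missing_rate = 0, seed = 59)
  post <- run_mcmc(g, mutation_model_by_name("EU1"), dem_kind = "CONSTANT",
                   n_iter = 60, burnin = 0.5, seed = 60, ess_warn = 0)
  k <- vapply(seq_len(3), function(j)
    length(unique(msatdemog:::gene_copies(g, j))), 0L)
  expect_equal(post$rate_modifiers, k / mean(k))
  expect_equal(mean(post$rate_modifiers), 1)
})
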