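test_that("the model family is the full 2 x 3 x 2 cross product", {
  nm <- msat_model_names()
  expect_length(nm, 12)
  expect_setequal(nm, c("EU1", "PU1", "EC1", "PC1", "EL1", "PL1",
                        "EU2", "PU2", "EC2", "PC2", "EL2", "PL2"))
  # law coercions
  m <- mutation_model("EQUAL", "UNBIASED", "MULTI_STEP", b0 = 3, b1 = 2, m = 0.4)
  expect_equal(c(m$b0, m$b1), c(0, 0))
  m2 <- mutation_model("EQUAL", "CONSTANT", "ONE_STEP", b0 = 1, b1 = 2)
  expect_equal(m2$b1, 0)
  expect_equal(m2$m, 1)
  expect_error(mutation_model(i_min = 5, i_max = 5), "two states")
  expect_error(mutation_model_by_name("XX1"), "unknown model")
})

test_that("rate matrices are proper generators for all 12 models", {
  for (nm in msat_model_names()) {
    Q <- build_rate_matrix(mutation_model_by_name(nm, i_min = 1, i_max = 15))
    expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-10)
    off <- Q; diag(off) <- 0
    expect_gte(min(off), 0)
    pi <- stationary_distribution(Q)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_equal(max(abs(pi %*% Q)), 0, tolerance = 1e-9)
    # stationary-weighted mean rate rescaled to one
    expect_equal(sum(pi * -diag(Q)), 1, tolerance = 1e-9)
  }
})

test_that("unscaled single-step construction matches the hand example", {
  # EU1 on [10, 12], alpha 1: interior rates 0.5 each way; the downward
  # move at the lower boundary is dropped
  Q <- build_rate_matrix(mutation_model_by_name("EU1", i_min = 10, i_max = 12),
                         rescale = FALSE)
  expect_equal(Q["10", "11"], 0.5)
  expect_equal(Q["10", "10"], -0.5)
  expect_equal(Q["11", "10"], 0.5)
  expect_equal(Q["11", "12"], 0.5)
  expect_equal(Q["12", "11"], 0.5)
  # unbiased => expansion probability one half everywhere
  m <- mutation_model_by_name("EU2")
  expect_equal(stats::plogis(m$b0), 0.5)
})

test_that("stationary distributions obey detailed-balance closed forms", {
  # EU1: symmetric birth-death -> uniform
  Q <- build_rate_matrix(mutation_model_by_name("EU1", i_min = 3, i_max = 12))
  expect_equal(unname(stationary_distribution(Q)), rep(0.1, 10),
               tolerance = 1e-9)
  # PU1: pi_i proportional to 1/(i - i_min + 1)
  Qp <- build_rate_matrix(mutation_model_by_name("PU1", i_min = 3, i_max = 12))
  pip <- stationary_distribution(Qp)
  expected <- (1 / (1:10)) / sum(1 / (1:10))
  expect_equal(unname(pip), expected, tolerance = 1e-9)
  # all one-step chains are reversible: pi_i q_ij = pi_j q_ji
  for (nm in c("EU1", "PU1", "EC1", "PC1", "EL1", "PL1")) {
    Q1 <- build_rate_matrix(mutation_model_by_name(nm, i_min = 1, i_max = 10))
    pi1 <- stationary_distribution(Q1)
    flux <- pi1 * Q1
    expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-10)
  }
  # constant expansion bias shifts the stationary mean upward
  Qu <- build_rate_matrix(mutation_model_by_name("EU1", i_min = 1, i_max = 20))
  Qc <- build_rate_matrix(mutation_model_by_name("EC1", i_min = 1, i_max = 20,
                                                 b0 = 1))
  states <- 1:20
  expect_gt(sum(states * stationary_distribution(Qc)),
            sum(states * stationary_distribution(Qu)))
})

test_that("transition probabilities form a stochastic semigroup", {
  for (nm in msat_model_names()) {
    Q <- build_rate_matrix(mutation_model_by_name(nm, i_min = 1, i_max = 12))
    P0 <- transition_probabilities(Q, 0)
    expect_equal(P0, diag(12), ignore_attr = TRUE, tolerance = 1e-10)
    P1 <- transition_probabilities(Q, 0.6)
    expect_equal(max(abs(rowSums(P1) - 1)), 0, tolerance = 1e-10)
    expect_gte(min(P1), 0)
    # Chapman-Kolmogorov
    Pa <- transition_probabilities(Q, 0.25)
    Pb <- transition_probabilities(Q, 0.35)
    expect_equal(Pa %*% Pb, P1, tolerance = 1e-8, ignore_attr = TRUE)
    # independent dense-exponential oracle
    expect_equal(P1, as.matrix(Matrix::expm(Matrix::Matrix(unclass(Q) * 0.6))),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(transition_probabilities(
    build_rate_matrix(mutation_model_by_name("EU1")), -1), ">= 0")
})

test_that("long branches forget the initial state", {
  Q <- build_rate_matrix(mutation_model_by_name("PC2", i_min = 1, i_max = 15))
  P <- transition_probabilities(Q, 1000)
  pi <- stationary_distribution(Q)
  expect_equal(max(abs(sweep(P, 2, pi))), 0, tolerance = 1e-8)
})

test_that("the multi-step law converges to one-step as m -> 1", {
  tr <- tree3(0.4, 0.9)
  tips <- c(6L, 8L, 7L)
  for (pair in list(c("EU2", "EU1"), c("PC2", "PC1"))) {
    Qm <- build_rate_matrix(mutation_model_by_name(pair[1], i_min = 1,
                                                   i_max = 12, m = 1 - 1e-9))
    Q1 <- build_rate_matrix(mutation_model_by_name(pair[2], i_min = 1,
                                                   i_max = 12))
    expect_equal(pruning_loglik(tips, tr, Qm), pruning_loglik(tips, tr, Q1),
                 tolerance = 1e-6)
  }
})

test_that("model specs load from lists and files", {
  m <- mutation_model_from_spec(list(name = "PC2", i_min = 2, i_max = 20,
                                     b0 = 0.8, m = 0.5))
  expect_equal(m$rate_law, "PROPORTIONAL")
  expect_equal(m$bias_law, "CONSTANT")
  expect_equal(c(m$b0, m$m, m$i_min, m$i_max), c(0.8, 0.5, 2, 20))
  m2 <- mutation_model_from_spec(list(rate_law = "EQUAL",
                                      bias_law = "LINEAR",
                                      step_law = "ONE_STEP",
                                      b0 = 1, b1 = -0.1))
  expect_equal(m2$b1, -0.1)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "EU2", i_max = 12), js, auto_unbox = TRUE)
  expect_equal(mutation_model_from_spec(js)$i_max, 12L)
  ym <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "EL1", b1 = -0.3), ym)
  expect_equal(mutation_model_from_spec(ym)$b1, -0.3)
})
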