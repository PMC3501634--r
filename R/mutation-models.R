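#' The twelve microsatellite mutation model names
#'
#' Models are the cross product of rate law (E = equal, P = proportional to
#' allele length), directional-bias law (U = unbiased, C = constant bias,
#' L = length-dependent logistic bias) and step law (1 = single step,
#' 2 = geometric multi-step).
#'
#' @return Character vector of the 12 model names (`"EU1"`, ..., `"PL2"`).
#' @export
msat_model_names <- function() {
  as.vector(outer(outer(c("E", "P"), c("U", "C", "L"), paste0),
                  c("1", "2"), paste0))
}

#' Specify a microsatellite mutation model
#'
#' Defines a continuous-time Markov chain on the bounded repeat-count
#' lattice `[i_min, i_max]`. The per-allele total mutation rate is `alpha`
#' (EQUAL) or `alpha * (i - i_min + 1)` (PROPORTIONAL). The probability that
#' a mutation expands the allele is a logistic function of lattice position,
#' `gamma_i = plogis(b0 + b1 * (i - i_min))`: UNBIASED forces `b0 = b1 = 0`
#' (so `gamma = 1/2` everywhere), CONSTANT forces `b1 = 0`, and LINEAR uses
#' both coefficients. Step sizes are 1 (ONE_STEP) or geometric with success
#' parameter `m` on `{1, 2, ...}` (MULTI_STEP; mean step `1/m`; `m = 1`
#' recovers the one-step model).
#'
#' @param rate_law `"EQUAL"` or `"PROPORTIONAL"`.
#' @param bias_law `"UNBIASED"`, `"CONSTANT"` or `"LINEAR"`.
#' @param step_law `"ONE_STEP"` or `"MULTI_STEP"`.
#' @param alpha Base mutation rate (rescaled away in [build_rate_matrix()]).
#' @param b0,b1 Logistic bias coefficients.
#' @param m Geometric step parameter in `(0, 1]`.
#' @param i_min,i_max Lattice bounds (defaults `[1, 35]`).
#' @return An object of class `"mutation_model"`.
#' @seealso [mutation_model_by_name()] for the Table-style short names.
#' @export
mutation_model <- function(rate_law = c("EQUAL", "PROPORTIONAL"),
                           bias_law = c("UNBIASED", "CONSTANT", "LINEAR"),
                           step_law = c("ONE_STEP", "MULTI_STEP"),
                           alpha = 1, b0 = 0, b1 = 0, m = 1,
                           i_min = 1L, i_max = 35L) {
  rate_law <- match.arg(rate_law)
  bias_law <- match.arg(bias_law)
  step_law <- match.arg(step_law)
  i_min <- as.integer(i_min); i_max <- as.integer(i_max)
  if (alpha <= 0) stop("alpha must be positive")
  if (i_max - i_min < 1L) stop("lattice must contain at least two states")
  if (m <= 0 || m > 1) stop("geometric step parameter m must be in (0, 1]")
  if (bias_law == "UNBIASED") { b0 <- 0; b1 <- 0 }
  if (bias_law == "CONSTANT") b1 <- 0
  if (step_law == "ONE_STEP") m <- 1
  structure(list(rate_law = rate_law, bias_law = bias_law,
                 step_law = step_law, alpha = alpha, b0 = b0, b1 = b1,
                 m = m, i_min = i_min, i_max = i_max),
            class = "mutation_model")
}

#' Build a mutation model from its short name
#'
#' @param name One of [msat_model_names()], e.g. `"PU2"`.
#' @param i_min,i_max Lattice bounds.
#' @param b0,b1 Bias coefficients used by the C/L models (defaults: a mild
#'   constant expansion bias `b0 = 0.5` for C; `b0 = 2, b1 = -0.2` for L,
#'   which favours expansion of short alleles and contraction of long ones).
#' @param m Geometric step parameter for the multi-step models (default
#'   `1/2.8`, mean step size 2.8).
#' @param alpha Base rate.
#' @return A [mutation_model()].
#' @export
mutation_model_by_name <- function(name, i_min = 1L, i_max = 35L,
                                   b0 = NULL, b1 = NULL, m = NULL,
                                   alpha = 1) {
  if (!(name %in% msat_model_names())) {
    stop(sprintf("unknown model '%s'; see msat_model_names()", name))
  }
  parts <- strsplit(name, "")[[1]]
  rate_law <- if (parts[1] == "E") "EQUAL" else "PROPORTIONAL"
  bias_law <- switch(parts[2], U = "UNBIASED", C = "CONSTANT", L = "LINEAR")
  step_law <- if (parts[3] == "1") "ONE_STEP" else "MULTI_STEP"
  if (is.null(b0)) b0 <- switch(bias_law, UNBIASED = 0, CONSTANT = 0.5, LINEAR = 2)
  if (is.null(b1)) b1 <- if (bias_law == "LINEAR") -0.2 else 0
  if (is.null(m)) m <- if (step_law == "MULTI_STEP") 1 / 2.8 else 1
  mutation_model(rate_law, bias_law, step_law, alpha = alpha,
                 b0 = b0, b1 = b1, m = m, i_min = i_min, i_max = i_max)
}

#' Build a mutation model from a specification list or file
#'
#' Accepts a named list (or a path to a JSON/YAML file holding one) with a
#' `name` entry (one of [msat_model_names()]) and/or explicit fields
#' `rate_law`, `bias_law`, `step_law`, `alpha`, `b0`, `b1`, `m`, `i_min`,
#' `i_max`; explicit fields override the name's defaults.
#'
#' @param spec Named list, or path to a `.json`/`.yaml` file.
#' @return A [mutation_model()].
#' @export
mutation_model_from_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    spec <- if (grepl("\\.ya?ml$", spec, ignore.case = TRUE)) {
      yaml::read_yaml(spec)
    } else {
      jsonlite::read_json(spec, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(spec))
  if (!is.null(spec$name)) {
    args <- spec[intersect(names(spec), c("i_min", "i_max", "b0", "b1", "m",
                                          "alpha"))]
    return(do.call(mutation_model_by_name, c(list(name = spec$name), args)))
  }
  args <- spec[intersect(names(spec), c("rate_law", "bias_law", "step_law",
                                        "alpha", "b0", "b1", "m",
                                        "i_min", "i_max"))]
  do.call(mutation_model, args)
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("mutation_model: %s / %s / %s on [%d, %d]\n",
              x$rate_law, x$bias_law, x$step_law, x$i_min, x$i_max))
  cat(sprintf("alpha = %g, b0 = %g, b1 = %g, m = %g\n",
              x$alpha, x$b0, x$b1, x$m))
  invisible(x)
}

#' Build the rate matrix of a mutation model
#'
#' Off-diagonal rates are `r_i * gamma_i * g(s)` upward and
#' `r_i * (1 - gamma_i) * g(s)` downward, with the geometric step
#' distribution truncated at the lattice boundary and renormalized within
#' each direction; at a boundary state the blocked direction's mass is
#' dropped entirely, so boundary states mutate at a reduced total rate.
#' The matrix is rescaled so the stationary-weighted mean mutation rate is
#' exactly 1, making branch lengths comparable across models.
#'
#' @param model A [mutation_model()].
#' @param rescale Rescale to stationary mean rate 1 (default `TRUE`).
#' @return A square rate matrix with `dimnames` the repeat counts, rows
#'   summing to zero, carrying attributes `i_min`, `i_max`, `model`, and
#'   `stationary` (the stationary distribution).
#' @export
build_rate_matrix <- function(model, rescale = TRUE) {
  stopifnot(inherits(model, "mutation_model"))
  states <- model$i_min:model$i_max
  S <- length(states)
  Q <- matrix(0, S, S, dimnames = list(states, states))
  pos <- states - model$i_min                      # lattice position 0-based
  gamma <- stats::plogis(model$b0 + model$b1 * pos)
  r <- if (model$rate_law == "EQUAL") rep(model$alpha, S) else
    model$alpha * (pos + 1)
  geom_w <- function(nstep) {
    if (nstep == 0L) return(numeric(0))
    if (model$step_law == "ONE_STEP") return(c(1, rep(0, nstep - 1L)))
    s <- seq_len(nstep)
    w <- (1 - model$m)^(s - 1) * model$m
    w / sum(w)
  }
  for (k in seq_len(S)) {
    up <- S - k; down <- k - 1L
    if (up > 0L) {
      w <- geom_w(up)
      Q[k, k + seq_len(up)] <- r[k] * gamma[k] * w
    }
    if (down > 0L) {
      w <- geom_w(down)
      Q[k, k - seq_len(down)] <- r[k] * (1 - gamma[k]) * w
    }
    Q[k, k] <- -sum(Q[k, -k])
  }
  pi <- stationary_from_matrix(Q)
  if (rescale) {
    mean_rate <- sum(pi * -diag(Q))
    Q <- Q / mean_rate
  }
  attr(Q, "i_min") <- model$i_min
  attr(Q, "i_max") <- model$i_max
  attr(Q, "model") <- model
  attr(Q, "stationary") <- pi
  Q
}

# stationary distribution by solving pi Q = 0, sum(pi) = 1 (least squares on
# the augmented system; exact for an irreducible finite chain)
stationary_from_matrix <- function(Q) {
  S <- nrow(Q)
  A <- rbind(t(Q), rep(1, S))
  b <- c(rep(0, S), 1)
  pi <- qr.solve(A, b)
  if (any(pi < -1e-8)) stop("rate matrix appears reducible: negative stationary mass")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  names(pi) <- rownames(Q)
  pi
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1`.
#'
#' @param Q A rate matrix from [build_rate_matrix()] (or any irreducible
#'   generator).
#' @return Named numeric vector over the lattice states.
#' @export
stationary_distribution <- function(Q) {
  pi <- attr(Q, "stationary")
  if (!is.null(pi)) return(pi)
  stationary_from_matrix(unclass(Q))
}

# Eigen-decomposition cache for repeated matrix exponentials exp(Qt).
# Complex arithmetic is used when the chain is non-reversible; the result is
# real up to round-off and the imaginary part is discarded.
ctmc_cache <- function(Q) {
  e <- eigen(Q)
  V <- e$vectors
  Vinv <- solve(V)
  # validate the decomposition; fall back to Matrix::expm if ill-conditioned
  ok <- {
    recon <- V %*% diag(e$values, nrow(Q)) %*% Vinv
    max(Mod(recon - Q)) < 1e-8
  }
  is_real <- is.numeric(e$values) ||
    max(abs(Im(e$values))) < 1e-12 && max(abs(Im(V))) < 1e-12
  if (is_real) {
    V <- Re(V); Vinv <- Re(Vinv); vals <- Re(e$values)
  } else {
    vals <- e$values
  }
  list(Q = unclass(Q), values = vals, V = V, Vinv = Vinv, ok = ok,
       is_real = is_real, pi = stationary_distribution(Q))
}

tpm_from_cache <- function(cache, t) {
  if (t < 0) stop("branch length t must be >= 0")
  if (!cache$ok) {
    return(as.matrix(Matrix::expm(Matrix::Matrix(cache$Q * t))))
  }
  P <- cache$V %*% (exp(cache$values * t) * cache$Vinv)
  P <- Re(P)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probabilities over a branch
#'
#' Computes `exp(Q t)` by eigen-decomposition (with a dense matrix
#' exponential fallback for ill-conditioned generators).
#'
#' @param Q A rate matrix.
#' @param t Branch length (expected mutations per lattice unit time), >= 0.
#' @return Row-stochastic matrix of the same dimension as `Q`.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("branch length t must be >= 0")
  tpm_from_cache(ctmc_cache(Q), t)
}
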