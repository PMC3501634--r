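#' Coalescent log density of a genealogy under a demography
#'
#' Standard time-inhomogeneous Kingman coalescent density on a labelled
#' genealogy: for each inter-event interval with `k` extant lineages the
#' exponent `-choose(k, 2) * integral(1/theta)`, and `-log theta(t_c)` at
#' each coalescence. Integrals are piecewise-exact for every supported
#' demography kind.
#'
#' @param tree A `"genealogy"`.
#' @param dem A [demography] object.
#' @return Log density (natural log).
#' @export
coalescent_loglik <- function(tree, dem) {
  n <- tree$n_tips
  ev <- sort(tree$time[(n + 1L):(2L * n - 1L)])
  k <- n:2
  ck2 <- k * (k - 1) / 2
  lo <- c(0, ev[-(n - 1L)])
  switch(dem$kind,
    CONSTANT = -sum(ck2 * (ev - lo)) / dem$theta - (n - 1) * log(dem$theta),
    EXPONENTIAL = {
      g <- dem$growth
      I <- if (abs(g) < 1e-12) (ev - lo) / dem$theta0 else
        (exp(g * ev) - exp(g * lo)) / (dem$theta0 * g)
      -sum(ck2 * I) - sum(log(dem$theta0) - g * ev)
    },
    PIECEWISE = {
      brk <- dem$times
      th <- dem$thetas
      cum <- c(0, cumsum(diff(c(0, brk)) / th[seq_along(brk)]))
      cum_i <- function(t) {
        idx <- findInterval(t, brk)
        cum[idx + 1L] + (t - c(0, brk)[idx + 1L]) / th[idx + 1L]
      }
      -sum(ck2 * (cum_i(ev) - cum_i(lo))) -
        sum(log(th[findInterval(ev, brk) + 1L]))
    })
}

#' Felsenstein pruning log likelihood of microsatellite tip states
#'
#' Computes the likelihood of the repeat counts at the tips of a genealogy
#' under a mutation-model CTMC, with the root weighted by the stationary
#' distribution. Missing tips (`NA`) carry an all-ones partial and so are
#' marginalized out. Branch transition matrices are
#' `exp(Q * rate_modifier * branch_length)`.
#'
#' @param tips Integer vector of repeat counts, one per tip; `NA` allowed.
#' @param tree A `"genealogy"` with `length(tips)` tips.
#' @param model A [mutation_model()] or a rate matrix from
#'   [build_rate_matrix()].
#' @param rate_modifier Per-locus rate multiplier.
#' @param cache Optional precomputed internal CTMC cache (for repeated
#'   evaluation).
#' @return Log likelihood.
#' @export
pruning_loglik <- function(tips, tree, model, rate_modifier = 1,
                           cache = NULL) {
  if (is.null(cache)) {
    Q <- if (inherits(model, "mutation_model")) build_rate_matrix(model) else model
    cache <- ctmc_cache(Q)
  }
  states <- as.integer(rownames(cache$Q))
  S <- length(states)
  n <- tree$n_tips
  stopifnot(length(tips) == n)
  bad <- !is.na(tips) & !(tips %in% states)
  if (any(bad)) stop("tip state(s) outside the model lattice")
  n_nodes <- 2L * n - 1L
  part <- matrix(1, S, n_nodes)
  obs <- which(!is.na(tips))
  part[, obs] <- 0
  part[cbind(match(tips[obs], states), obs)] <- 1
  logscale <- 0
  internal <- which(!is.na(tree$children[, 1]))
  internal <- internal[order(tree$time[internal])]  # children before parents
  # exp(Qt) %*% v through the eigenbasis: V (exp(vals t) * (Vinv v)),
  # avoiding the full transition matrix on every branch
  fast <- cache$ok
  real <- isTRUE(cache$is_real)
  V <- cache$V; Vinv <- cache$Vinv; vals <- cache$values
  ttime <- tree$time
  tch <- tree$children
  for (v in internal) {
    acc <- rep(1, S)
    for (ch in tch[v, ]) {
      len <- (ttime[v] - ttime[ch]) * rate_modifier
      pv <- if (fast && real) {
        as.vector(V %*% (exp(vals * len) * (Vinv %*% part[, ch])))
      } else if (fast) {
        as.vector(Re(V %*% (exp(vals * len) * (Vinv %*% part[, ch]))))
      } else {
        as.vector(tpm_from_cache(cache, len) %*% part[, ch])
      }
      pv[pv < 0] <- 0
      acc <- acc * pv
    }
    m <- max(acc)
    if (m <= 0) return(-Inf)
    part[, v] <- acc / m
    logscale <- logscale + log(m)
  }
  root <- genealogy_root(tree)
  log(sum(cache$pi * part[, root])) + logscale
}

#' Prior configuration for demographic inference
#'
#' @param lambda Poisson mean for the number of change points `psi`
#'   (default `log(2) = 0.6931`, which puts probability one half on no
#'   change at all).
#' @param psi_max Truncation for `psi` (the Poisson tail above it is
#'   negligible at the default `lambda`).
#' @param phi_bounds Bounds making the one-on-x prior on the segment-mean
#'   `phi` proper.
#' @param theta_bounds Bounds for the one-on-x (Jeffreys) prior on the
#'   constant-model `theta`.
#' @param t_max Upper bound of the change-point window; `NULL` (default)
#'   sets it at run time to the height of the tallest initial genealogy,
#'   since deeper change points cannot be informed by the data.
#' @param rate_modifiers `"fixed"` scales each locus's rate by its observed
#'   allele count (normalized to mean 1); `"none"` uses rate 1 everywhere.
#' @return List of class `"prior_config"`.
#' @export
prior_config <- function(lambda = log(2), psi_max = 20L,
                         phi_bounds = c(1e-4, 1e3),
                         theta_bounds = c(1e-4, 1e3),
                         t_max = NULL,
                         rate_modifiers = c("fixed", "none")) {
  stopifnot(lambda > 0, psi_max >= 1L, phi_bounds[1] > 0,
            phi_bounds[2] > phi_bounds[1], theta_bounds[1] > 0,
            theta_bounds[2] > theta_bounds[1])
  structure(list(lambda = lambda, psi_max = as.integer(psi_max),
                 phi_bounds = phi_bounds, theta_bounds = theta_bounds,
                 t_max = t_max,
                 rate_modifiers = match.arg(rate_modifiers)),
            class = "prior_config")
}

log_one_on_x <- function(x, bounds) {
  ifelse(x < bounds[1] | x > bounds[2], -Inf,
         -log(x) - log(log(bounds[2] / bounds[1])))
}

# demography object for the current skyline state
skyline_dem <- function(s, thetas) {
  if (length(s) == 0L) constant_demography(thetas) else
    piecewise_demography(s, thetas)
}

# ---- the sampler ------------------------------------------------------------

#' Bayesian skyline / constant-size MCMC over microsatellite genotypes
#'
#' Metropolis-within-Gibbs sampler for multi-locus coalescent inference.
#' Latent per-locus genealogies (for the `2N` exchangeable gene copies of
#' the diploid genotypes) are updated by node-height slides, subtree
#' exchanges and whole-tree scalings; the demographic model is either a
#' constant size `theta` with a bounded Jeffreys (one-on-x) prior, or a
#' piecewise-constant skyline whose number of change points `psi` has a
#' Poisson prior and is sampled by reversible-jump birth/death moves, with
#' segment sizes exponential around a mean `phi` that itself has a bounded
#' one-on-x prior. A joint up-down scaling move keeps sizes and genealogy
#' heights mixing together.
#'
#' @param g A [genotype_matrix()].
#' @param model A [mutation_model()] shared by all loci.
#' @param dem_kind `"CONSTANT"` or `"SKYLINE"`.
#' @param priors A [prior_config()].
#' @param n_iter Number of MCMC sweeps.
#' @param burnin Fraction of sweeps discarded (default 0.1).
#' @param thin Keep every `thin`-th sweep; `NULL` targets <= 2000 retained
#'   samples.
#' @param power Power-posterior exponent on the likelihood (1 = posterior,
#'   0 = prior); used for stepping-stone marginal likelihoods.
#' @param sample_prior If `TRUE`, the mutation likelihood is forced to 1
#'   and only the joint prior is sampled.
#' @param seed Optional RNG seed.
#' @param ess_warn Warn when the effective sample size of the `lnL` trace
#'   falls below this (default 50).
#' @return An object of class `"skyline_posterior"`: list with `samples`
#'   (data frame `lnL`, `psi`, `phi`, `theta0`, `TCOAL`), `traj` (list of
#'   per-sample `times`/`thetas`), `dem_kind`, `priors`, `t_max`,
#'   `acceptance`, `rate_modifiers`.
#' @export
run_mcmc <- function(g, model, dem_kind = c("SKYLINE", "CONSTANT"),
                     priors = prior_config(), n_iter = 2000L,
                     burnin = 0.1, thin = NULL, power = 1,
                     sample_prior = FALSE, seed = NULL, ess_warn = 50) {
  dem_kind <- match.arg(dem_kind)
  if (!is.null(seed)) set.seed(seed)
  if (n_iter < 10L || burnin < 0 || burnin >= 1) {
    stop("invalid chain settings")
  }
  if (sample_prior) power <- 0
  L <- n_loci(g)
  Q <- build_rate_matrix(model)
  cache <- ctmc_cache(Q)

  # per-locus tip states (gene copies of genotyped individuals)
  tips <- lapply(seq_len(L), function(j) {
    ok <- !is.na(g$a1[, j])
    as.integer(rbind(g$a1[ok, j], g$a2[ok, j]))
  })
  sizes <- vapply(tips, length, 0L)
  if (any(sizes < 2L)) stop("every locus needs at least one genotyped individual")
  k_obs <- vapply(seq_len(L), function(j) length(unique(tips[[j]])), 0L)
  if (power > 0 && all(k_obs < 2L)) stop("need at least one polymorphic locus")
  rate_mod <- if (priors$rate_modifiers == "fixed") {
    k_obs / mean(k_obs)
  } else rep(1, L)

  # moment initialization: Var(allele size) estimates theta under stepwise
  # mutation; clip into the prior support
  v <- mean(vapply(seq_len(L), function(j) stats::var(as.numeric(tips[[j]])), 0))
  th0 <- min(max(v, priors$theta_bounds[1] * 2), priors$theta_bounds[2] / 2)
  if (!is.finite(th0) || th0 <= 0) th0 <- 1

  trees <- lapply(seq_len(L), function(j) {
    simulate_genealogy(sizes[j], constant_demography(th0))
  })
  # Change points deeper than the tallest genealogy are likelihood-neutral,
  # so the default window stops at the initial tallest root height.
  t_max <- priors$t_max
  if (is.null(t_max)) t_max <- max(vapply(trees, root_height, 0))

  # state
  psi <- 0L
  s <- numeric(0)
  thetas <- th0          # skyline segments (length psi + 1), or constant theta
  phi <- th0
  dem <- skyline_dem(s, thetas)

  plik <- function(j, tree) {
    if (power == 0) 0 else
      pruning_loglik(tips[[j]], tree, Q, rate_mod[j], cache = cache)
  }
  lik <- vapply(seq_len(L), function(j) plik(j, trees[[j]]), 0)
  coal <- vapply(seq_len(L), function(j) coalescent_loglik(trees[[j]], dem), 0)

  theta_prior <- function(thetas, phi) {
    if (dem_kind == "CONSTANT") {
      log_one_on_x(thetas, priors$theta_bounds)
    } else {
      sum(stats::dexp(thetas, 1 / phi, log = TRUE)) +
        log_one_on_x(phi, priors$phi_bounds)
    }
  }

  if (is.null(thin)) thin <- max(1L, ceiling(n_iter * (1 - burnin) / 2000))
  keep_from <- floor(n_iter * burnin) + 1L
  acc <- prop <- c(slide = 0, exchange = 0, resim = 0, scale = 0,
                   theta = 0, stime = 0, birth = 0, death = 0, phi = 0,
                   updown = 0)
  rec <- list()
  traj <- list()

  for (it in seq_len(n_iter)) {
    # ---- tree moves, one locus at a time
    for (j in seq_len(L)) {
      tr <- trees[[j]]
      n <- tr$n_tips
      internal <- (n + 1L):(2L * n - 1L)
      # node slide / root gap multiplier
      v_node <- if (n == 2L) internal else sample(internal, 1L)
      lo <- max(tr$time[tr$children[v_node, ]])
      par <- tr$parent[v_node]
      prop["slide"] <- prop["slide"] + 1
      tr2 <- tr
      lhast <- 0
      if (par == 0L) {
        gap <- tr$time[v_node] - lo
        mfac <- exp(0.8 * (stats::runif(1) - 0.5))
        tr2$time[v_node] <- lo + gap * mfac
        lhast <- log(mfac)
      } else {
        tr2$time[v_node] <- stats::runif(1, lo, tr$time[par])
      }
      lik2 <- plik(j, tr2)
      coal2 <- coalescent_loglik(tr2, dem)
      if (log(stats::runif(1)) <
          power * (lik2 - lik[j]) + coal2 - coal[j] + lhast) {
        trees[[j]] <- tr2; lik[j] <- lik2; coal[j] <- coal2
        acc["slide"] <- acc["slide"] + 1
      }
      # narrow exchange (needs >= 3 tips and a non-root internal node)
      if (n >= 3L) {
        tr <- trees[[j]]
        nonroot <- internal[tr$parent[internal] != 0L]
        if (length(nonroot)) {
          prop["exchange"] <- prop["exchange"] + 1
          p <- if (length(nonroot) == 1L) nonroot else sample(nonroot, 1L)
          gp <- tr$parent[p]
          sibs <- tr$children[gp, ]
          b <- sibs[sibs != p]
          a <- tr$children[p, sample(1:2, 1L)]
          if (tr$time[b] < tr$time[p]) {
            tr2 <- tr
            slot_a <- which(tr$children[p, ] == a)
            slot_b <- which(tr$children[gp, ] == b)
            tr2$children[p, slot_a] <- b
            tr2$children[gp, slot_b] <- a
            tr2$parent[b] <- p
            tr2$parent[a] <- gp
            lik2 <- plik(j, tr2)
            if (log(stats::runif(1)) < power * (lik2 - lik[j])) {
              trees[[j]] <- tr2; lik[j] <- lik2
              acc["exchange"] <- acc["exchange"] + 1
            }
          }
        }
      }
      # independence redraw from the coalescent prior: proposal density is
      # the genealogy prior itself, so only the likelihood ratio remains
      prop["resim"] <- prop["resim"] + 1
      tr2 <- simulate_genealogy(sizes[j], dem)
      lik2 <- plik(j, tr2)
      if (log(stats::runif(1)) < power * (lik2 - lik[j])) {
        trees[[j]] <- tr2; lik[j] <- lik2
        coal[j] <- coalescent_loglik(tr2, dem)
        acc["resim"] <- acc["resim"] + 1
      }
      # whole-tree scale
      tr <- trees[[j]]
      prop["scale"] <- prop["scale"] + 1
      mfac <- exp(0.5 * (stats::runif(1) - 0.5))
      tr2 <- tr
      tr2$time[internal] <- tr$time[internal] * mfac
      lik2 <- plik(j, tr2)
      coal2 <- coalescent_loglik(tr2, dem)
      if (log(stats::runif(1)) < power * (lik2 - lik[j]) + coal2 - coal[j] +
          (n - 1) * log(mfac)) {
        trees[[j]] <- tr2; lik[j] <- lik2; coal[j] <- coal2
        acc["scale"] <- acc["scale"] + 1
      }
    }

    coal_total <- function(d) {
      vapply(seq_len(L), function(j) coalescent_loglik(trees[[j]], d), 0)
    }

    # ---- constant model: exact Gibbs draw of theta.
    # The coalescent factor is theta^-(n_events) exp(-A/theta) with
    # A = sum over intervals of choose(k,2) dt; with the 1/theta prior,
    # 1/theta | trees ~ Gamma(n_events, rate = A) truncated to the bounds.
    if (dem_kind == "CONSTANT") {
      A <- sum(vapply(trees, function(tr) {
        n <- tr$n_tips
        ev <- sort(tr$time[(n + 1L):(2L * n - 1L)])
        ks <- n:2
        sum(ks * (ks - 1) / 2 * diff(c(0, ev)))
      }, 0))
      a_shape <- sum(sizes - 1L)
      xlo <- 1 / priors$theta_bounds[2]
      xhi <- 1 / priors$theta_bounds[1]
      Flo <- stats::pgamma(xlo, a_shape, rate = A)
      Fhi <- stats::pgamma(xhi, a_shape, rate = A)
      if (Fhi - Flo > 1e-12) {
        x <- stats::qgamma(stats::runif(1, Flo, Fhi), a_shape, rate = A)
        thetas <- 1 / x
        dem <- skyline_dem(s, thetas)
        coal <- coal_total(dem)
      }
    }

    # ---- size-segment multiplier (cheap; repeated for better mixing)
    for (rep_theta in 1:2) {
      prop["theta"] <- prop["theta"] + 1
      jseg <- sample.int(length(thetas), 1L)
      mfac <- exp(1.6 * (stats::runif(1) - 0.5))
      th2 <- thetas; th2[jseg] <- thetas[jseg] * mfac
      ok_bounds <- dem_kind != "CONSTANT" ||
        (th2 >= priors$theta_bounds[1] && th2 <= priors$theta_bounds[2])
      if (ok_bounds) {
        dem2 <- skyline_dem(s, th2)
        coal2 <- coal_total(dem2)
        dpr <- theta_prior(th2, phi) - theta_prior(thetas, phi)
        if (log(stats::runif(1)) < sum(coal2 - coal) + dpr + log(mfac)) {
          thetas <- th2; dem <- dem2; coal <- coal2
          acc["theta"] <- acc["theta"] + 1
        }
      }
    }

    if (dem_kind == "SKYLINE") {
      # ---- change-time slide
      if (psi >= 1L) {
        prop["stime"] <- prop["stime"] + 1
        i <- sample.int(psi, 1L)
        w <- t_max / 10
        si <- s[i] + stats::runif(1, -w, w)
        lo <- if (i == 1L) 0 else s[i - 1L]
        hi <- if (i == psi) t_max else s[i + 1L]
        if (si > lo && si < hi) {
          s2 <- s; s2[i] <- si
          dem2 <- skyline_dem(s2, thetas)
          coal2 <- coal_total(dem2)
          if (log(stats::runif(1)) < sum(coal2 - coal)) {
            s <- s2; dem <- dem2; coal <- coal2
            acc["stime"] <- acc["stime"] + 1
          }
        }
      }
      # ---- reversible-jump birth / death (cheap; repeated for psi mixing)
      for (rep_rj in 1:3) {
      if (stats::runif(1) < 0.5) {
        if (psi < priors$psi_max) {
          prop["birth"] <- prop["birth"] + 1
          s_star <- stats::runif(1, 0, t_max)
          th_star <- stats::rexp(1, 1 / phi)
          pos <- findInterval(s_star, s) + 1L   # segment being split
          s2 <- sort(c(s, s_star))
          th2 <- append(thetas, th_star, after = pos)
          dem2 <- skyline_dem(s2, th2)
          coal2 <- coal_total(dem2)
          # proposal from the prior: everything cancels except the Poisson
          # ratio and the coalescent term
          if (log(stats::runif(1)) <
              log(priors$lambda) - log(psi + 1) + sum(coal2 - coal)) {
            psi <- psi + 1L; s <- s2; thetas <- th2
            dem <- dem2; coal <- coal2
            acc["birth"] <- acc["birth"] + 1
          }
        }
      } else if (psi >= 1L) {
        prop["death"] <- prop["death"] + 1
        i <- sample.int(psi, 1L)
        s2 <- s[-i]
        th2 <- thetas[-(i + 1L)]    # the older side's segment is absorbed
        dem2 <- skyline_dem(s2, th2)
        coal2 <- coal_total(dem2)
        if (log(stats::runif(1)) <
            log(psi) - log(priors$lambda) + sum(coal2 - coal)) {
          psi <- psi - 1L; s <- s2; thetas <- th2
          dem <- dem2; coal <- coal2
          acc["death"] <- acc["death"] + 1
        }
      }
      }
      # ---- phi multiplier
      prop["phi"] <- prop["phi"] + 1
      mfac <- exp(1.2 * (stats::runif(1) - 0.5))
      phi2 <- phi * mfac
      if (phi2 >= priors$phi_bounds[1] && phi2 <= priors$phi_bounds[2]) {
        dpr <- theta_prior(thetas, phi2) - theta_prior(thetas, phi)
        if (log(stats::runif(1)) < dpr + log(mfac)) {
          phi <- phi2
          acc["phi"] <- acc["phi"] + 1
        }
      }
    }

    # ---- joint up-down scale: sizes, change times, genealogy heights
    prop["updown"] <- prop["updown"] + 1
    mfac <- exp(0.4 * (stats::runif(1) - 0.5))
    th2 <- thetas * mfac
    phi2 <- if (dem_kind == "SKYLINE") phi * mfac else phi
    s2 <- s * mfac
    ok_bounds <- if (dem_kind == "CONSTANT") {
      th2 >= priors$theta_bounds[1] && th2 <= priors$theta_bounds[2]
    } else {
      phi2 >= priors$phi_bounds[1] && phi2 <= priors$phi_bounds[2] &&
        all(s2 <= t_max)
    }
    if (ok_bounds) {
      trees2 <- lapply(trees, function(tr) {
        n <- tr$n_tips
        tr$time[(n + 1L):(2L * n - 1L)] <- tr$time[(n + 1L):(2L * n - 1L)] * mfac
        tr
      })
      dem2 <- skyline_dem(s2, th2)
      lik2 <- vapply(seq_len(L), function(j) plik(j, trees2[[j]]), 0)
      coal2 <- vapply(seq_len(L), function(j) coalescent_loglik(trees2[[j]], dem2), 0)
      npar <- length(th2) + length(s2) + sum(sizes - 1L) +
        (dem_kind == "SKYLINE")
      dpr <- theta_prior(th2, phi2) - theta_prior(thetas, phi)
      if (log(stats::runif(1)) < power * sum(lik2 - lik) +
          sum(coal2 - coal) + dpr + npar * log(mfac)) {
        thetas <- th2; phi <- phi2; s <- s2; trees <- trees2
        dem <- dem2; lik <- lik2; coal <- coal2
        acc["updown"] <- acc["updown"] + 1
      }
    }

    if (it >= keep_from && (it - keep_from) %% thin == 0L) {
      rec[[length(rec) + 1L]] <- c(
        lnL = sum(lik), psi = psi, phi = if (dem_kind == "SKYLINE") phi else NA,
        theta0 = thetas[1], TCOAL = max(vapply(trees, root_height, 0)))
      traj[[length(traj) + 1L]] <- list(times = s, thetas = thetas)
    }
  }

  samples <- as.data.frame(do.call(rbind, rec))
  e <- ess(samples$lnL)
  if (power > 0 && is.finite(e) && e < ess_warn) {
    warning(sprintf("low effective sample size of lnL trace: %.0f", e))
  }
  structure(list(samples = samples, traj = traj, dem_kind = dem_kind,
                 priors = priors, t_max = t_max,
                 acceptance = ifelse(prop > 0, acc / pmax(prop, 1), NA),
                 rate_modifiers = rate_mod, n_iter = n_iter, thin = thin,
                 power = power),
            class = "skyline_posterior")
}

# crude autocorrelation-time effective sample size
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] else length(ac)
  tau <- 1 + 2 * sum(ac[seq_len(cut)])
  n / max(tau, 1)
}

#' @export
print.skyline_posterior <- function(x, ...) {
  cat(sprintf("skyline_posterior (%s): %d retained samples\n",
              x$dem_kind, nrow(x$samples)))
  if (x$dem_kind == "SKYLINE") {
    pm <- table(x$samples$psi) / nrow(x$samples)
    cat("psi posterior:", paste(sprintf("%s:%.2f", names(pm), pm),
                                collapse = " "), "\n")
  }
  cat(sprintf("mean theta(0) = %.4g; mean T_COAL = %.4g\n",
              mean(x$samples$theta0), mean(x$samples$TCOAL)))
  invisible(x)
}

#' Write a posterior trace as a tab-separated log file
#'
#' One row per retained sample with `state`, `lnL`, `psi`, `phi`, `theta0`,
#' `TCOAL`, loadable by standard trace viewers.
#'
#' @param post A `"skyline_posterior"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(post, path) {
  df <- cbind(state = seq_len(nrow(post$samples)) - 1L, post$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shortest (highest-density) interval of a sample
#'
#' @param x Numeric sample.
#' @param prob Probability mass (default 0.95).
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Marginal-likelihood estimation
#'
#' `HARMONIC_MEAN` applies the harmonic-mean identity to a posterior `lnL`
#' trace, computed in log space with max-shift stabilization; its Monte
#' Carlo error is a block-bootstrap standard error. `STEPPING_STONE` sums
#' log mean importance ratios between adjacent power posteriors: supply
#' `x = list(traces = <list of lnL vectors>, betas = <0 = b1 < ... < 1>)`
#' where `traces[[k]]` was sampled at power `betas[k]` (the run at
#' `beta = 1` is not needed). At least 4 power runs are required.
#'
#' @param x A `"skyline_posterior"`, a numeric `lnL` trace, or the
#'   stepping-stone list described above.
#' @param method `"HARMONIC_MEAN"` or `"STEPPING_STONE"`.
#' @return List with `lnml` and `se`.
#' @export
estimate_lnml <- function(x, method = c("HARMONIC_MEAN", "STEPPING_STONE")) {
  method <- match.arg(method)
  logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  if (method == "HARMONIC_MEAN") {
    lnl <- if (inherits(x, "skyline_posterior")) x$samples$lnL else as.numeric(x)
    n <- length(lnl)
    if (n < 10L) stop("need a posterior lnL trace")
    hm <- function(v) log(length(v)) - logsumexp(-v)
    nb <- 10L
    blocks <- split(lnl, cut(seq_len(n), nb, labels = FALSE))
    boot <- replicate(200, hm(unlist(blocks[sample.int(nb, nb, replace = TRUE)])))
    list(lnml = hm(lnl), se = stats::sd(boot))
  } else {
    if (!is.list(x) || is.null(x$traces) || is.null(x$betas)) {
      stop("stepping stone needs list(traces = , betas = )")
    }
    K <- length(x$traces)
    if (K < 4L) stop("stepping stone requires at least 4 power-posterior runs")
    betas <- x$betas
    if (length(betas) != K + 1L || abs(betas[1]) > 1e-12 ||
        abs(betas[K + 1L] - 1) > 1e-12 || any(diff(betas) <= 0)) {
      stop("betas must be an increasing grid from 0 to 1 with one entry per trace plus the endpoint")
    }
    terms <- ses <- numeric(K)
    for (k in seq_len(K)) {
      d <- (betas[k + 1L] - betas[k]) * x$traces[[k]]
      terms[k] <- logsumexp(d) - log(length(d))
      # delta-method MC error of each log mean importance ratio
      w <- exp(d - max(d))
      ses[k] <- stats::sd(w) / (mean(w) * sqrt(length(w)))
    }
    list(lnml = sum(terms), se = sqrt(sum(ses^2)), terms = terms)
  }
}

#' Run power posteriors for stepping-stone estimation
#'
#' @param g,model,dem_kind,priors,n_iter,burnin,seed As in [run_mcmc()].
#' @param K Number of power runs.
#' @param alpha Beta-quantile spacing exponent: `betas = (k/K)^(1/alpha)`
#'   (default 0.3, concentrating runs near the prior).
#' @return A list suitable for [estimate_lnml()] with
#'   `method = "STEPPING_STONE"`.
#' @export
run_power_posteriors <- function(g, model, dem_kind = "CONSTANT",
                                 priors = prior_config(), n_iter = 2000L,
                                 burnin = 0.2, K = 8L, alpha = 0.3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  betas <- (seq(0, K) / K)^(1 / alpha)
  traces <- lapply(seq_len(K), function(k) {
    run_mcmc(g, model, dem_kind = dem_kind, priors = priors,
             n_iter = n_iter, burnin = burnin, power = betas[k],
             ess_warn = 0)$samples$lnL
  })
  list(traces = traces, betas = betas)
}

#' Rank models by log marginal likelihood
#'
#' `ln BF_i = ln mL_best - ln mL_i`; a ln BF above 5 is conventionally
#' labelled decisive.
#'
#' @param lnmls Named numeric vector of log marginal likelihoods.
#' @param decisive_threshold Label threshold (default 5).
#' @return Data frame of class `"model_comparison"`, ranked best first,
#'   with columns `model`, `lnml`, `lnBF`, `decisive`.
#' @export
compare_models <- function(lnmls, decisive_threshold = 5) {
  if (length(lnmls) < 2L) stop("need at least two models")
  ord <- order(lnmls, decreasing = TRUE)
  out <- data.frame(model = names(lnmls)[ord], lnml = unname(lnmls[ord]),
                    stringsAsFactors = FALSE)
  out$lnBF <- out$lnml[1] - out$lnml
  out$decisive <- out$lnBF > decisive_threshold
  class(out) <- c("model_comparison", class(out))
  out
}

#' Summarize a skyline posterior
#'
#' @param post A `"skyline_posterior"` with at least 100 retained samples.
#' @param grid Time points (before present) at which to summarize
#'   `theta(t)`; defaults to 25 points up to the median sampled `T_COAL`.
#'   Points beyond every sampled root height are dropped with a warning.
#' @param prob HPD mass.
#' @return List with `skyline` (data frame `time`, `mean`, `median`,
#'   `lower`, `upper`), `tcoal` (mean and HPD), and `psi_posterior`
#'   (probability table).
#' @export
summarize_posterior <- function(post, grid = NULL, prob = 0.95) {
  if (nrow(post$samples) < 100L) stop("need at least 100 retained samples")
  tc <- post$samples$TCOAL
  if (is.null(grid)) grid <- seq(0, stats::median(tc), length.out = 25)
  if (any(grid > max(tc))) {
    warning("grid truncated to the tallest sampled genealogy")
    grid <- grid[grid <= max(tc)]
  }
  th_at <- vapply(post$traj, function(tr) {
    idx <- findInterval(grid, tr$times) + 1L
    tr$thetas[idx]
  }, numeric(length(grid)))
  th_at <- matrix(th_at, nrow = length(grid))
  sk <- data.frame(time = grid,
                   mean = rowMeans(th_at),
                   median = apply(th_at, 1, stats::median),
                   lower = apply(th_at, 1, function(v) hpd_interval(v, prob)[1]),
                   upper = apply(th_at, 1, function(v) hpd_interval(v, prob)[2]))
  psi_tab <- table(factor(post$samples$psi,
                          levels = 0:max(post$samples$psi))) / nrow(post$samples)
  list(skyline = sk,
       tcoal = c(mean = mean(tc), hpd_interval(tc, prob)),
       psi_posterior = psi_tab)
}

#' Write a skyline summary table as TSV
#' @param summary Output of [summarize_posterior()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_skyline_tsv <- function(summary, path) {
  utils::write.table(summary$skyline, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
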