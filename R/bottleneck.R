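#' Two-phase mutation model parameters
#'
#' Under the two-phase model (TPM) a mutation is a single repeat step with
#' probability `p_single` and otherwise a multi-step change whose size
#' follows a geometric distribution on `{1, 2, ...}`. The geometric law can
#' be stated either through its variance (the BOTTLENECK convention,
#' recommended value 12) or its mean (the M_P_VAL convention, recommended
#' value 2.8); either is converted internally to the geometric success
#' parameter `q` (mean `1/q`, variance `(1 - q)/q^2`).
#'
#' @param p_single Probability that a mutation is a single step (default
#'   0.88, the M_P_VAL recommendation).
#' @param step_mean Mean multi-step size (default 2.8); mutually exclusive
#'   with `step_variance`.
#' @param step_variance Variance of the multi-step size (e.g. 12).
#' @return An object of class `"tpm_params"` with fields `p_single` and `q`.
#' @export
tpm_params <- function(p_single = 0.88, step_mean = 2.8,
                       step_variance = NULL) {
  if (p_single < 0 || p_single > 1) stop("p_single must be in [0, 1]")
  if (!is.null(step_variance)) {
    if (step_variance <= 0) stop("step_variance must be positive")
    # (1 - q)/q^2 = v  =>  q = (-1 + sqrt(1 + 4 v)) / (2 v)
    q <- (-1 + sqrt(1 + 4 * step_variance)) / (2 * step_variance)
  } else {
    if (is.null(step_mean) || step_mean < 1) {
      stop("step_mean must be >= 1")
    }
    q <- 1 / step_mean
  }
  structure(list(p_single = p_single, q = q), class = "tpm_params")
}

#' Draw signed mutation steps under the two-phase model
#'
#' @param params A [tpm_params()].
#' @param n Number of draws.
#' @return Integer vector of signed steps (never 0); signs are equiprobable.
#' @export
tpm_step <- function(params, n = 1L) {
  stopifnot(inherits(params, "tpm_params"))
  single <- stats::runif(n) < params$p_single
  size <- integer(n)
  size[single] <- 1L
  k <- sum(!single)
  if (k) size[!single] <- stats::rgeom(k, params$q) + 1L
  sign <- sample(c(-1L, 1L), n, replace = TRUE)
  sign * size
}

# One coalescent sample of n gene copies under the TPM: genealogy (constant
# theta, or any demography object), Poisson(branch length) mutations, tip
# value = sum of signed steps from the root (free lattice; only relative
# sizes matter).
sim_tpm_sample <- function(n, theta, params) {
  dem <- if (inherits(theta, "demography")) theta else
    constant_demography(theta)
  tree <- simulate_genealogy(n, dem)
  val <- numeric(length(tree$parent))
  root <- genealogy_root(tree)
  stack <- root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree$children[v, ]
    if (is.na(kids[1])) next
    for (ch in kids) {
      len <- tree$time[v] - tree$time[ch]
      nmut <- stats::rpois(1, len)
      delta <- if (nmut) sum(tpm_step(params, nmut)) else 0
      val[ch] <- val[v] + delta
      stack <- c(stack, ch)
    }
  }
  as.integer(val[seq_len(tree$n_tips)])
}

unbiased_het <- function(copies) {
  two_n <- length(copies)
  p <- as.numeric(table(copies)) / two_n
  if (two_n <= 1) return(0)
  (two_n / (two_n - 1)) * (1 - sum(p^2))
}

# Tune theta by bisection so that the mean simulated allele count matches k;
# returns theta. Mean k is monotone increasing in theta.
tune_theta_for_k <- function(n, k, params, n_tune = 60L,
                             lo = 0.01, hi = 200) {
  mean_k <- function(th) {
    mean(replicate(n_tune, length(unique(sim_tpm_sample(n, th, params)))))
  }
  for (iter in 1:18) {
    mid <- sqrt(lo * hi)
    if (mean_k(mid) < k) lo <- mid else hi <- mid
    if (hi / lo < 1.15) break
  }
  sqrt(lo * hi)
}

#' Heterozygote-excess bottleneck test under the TPM
#'
#' For each polymorphic locus, equilibrium samples are simulated under the
#' two-phase mutation model conditioned on the observed allele count `k`
#' (rejection sampling, with the simulation theta tuned by bisection so that
#' `k` is typical), giving the null distribution of expected heterozygosity
#' at mutation-drift equilibrium. The standardized excess
#' `DH = (He_obs - mean(He_eq)) / sd(He_eq)` is combined across loci by a
#' one-tailed Wilcoxon signed-rank test for excess, the signature of a
#' recent bottleneck.
#'
#' @param g A [genotype_matrix()].
#' @param params A [tpm_params()].
#' @param n_sim Conditioned simulations per locus.
#' @param max_attempts_factor Bounded rejection: at most
#'   `max_attempts_factor * n_sim` tries per locus before it is dropped.
#' @param seed Optional RNG seed.
#' @return List with `per_locus` (data frame: `locus`, `k`, `He_obs`,
#'   `He_eq_mean`, `He_eq_sd`, `DH`), `p_wilcoxon` (one-tailed, excess), and
#'   `n_loci_used`.
#' @export
het_excess_test <- function(g, params = tpm_params(), n_sim = 500L,
                            max_attempts_factor = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(g)
  rows <- list()
  for (j in seq_len(L)) {
    copies <- gene_copies(g, j)
    k <- length(unique(copies))
    if (k < 2L) next
    n <- length(copies)
    he_obs <- unbiased_het(copies)
    th <- tune_theta_for_k(n, k, params)
    he_eq <- numeric(0)
    attempts <- 0L
    while (length(he_eq) < n_sim && attempts < max_attempts_factor * n_sim) {
      attempts <- attempts + 1L
      s <- sim_tpm_sample(n, th, params)
      if (length(unique(s)) == k) he_eq <- c(he_eq, unbiased_het(s))
    }
    if (length(he_eq) < max(20L, n_sim %/% 10L)) {
      warning(sprintf("locus %s: conditioning on k = %d failed; dropped",
                      locus_names(g)[j], k))
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(locus = locus_names(g)[j], k = k, He_obs = he_obs,
                 He_eq_mean = mean(he_eq), He_eq_sd = stats::sd(he_eq),
                 stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) < 4L) {
    stop("need at least 4 polymorphic loci for the Wilcoxon test")
  }
  per$DH <- (per$He_obs - per$He_eq_mean) / per$He_eq_sd
  wt <- suppressWarnings(stats::wilcox.test(per$DH, alternative = "greater"))
  list(per_locus = per, p_wilcoxon = wt$p.value, n_loci_used = nrow(per))
}

#' Allele-frequency mode-shift descriptor
#'
#' Pools allele frequencies across loci into ten bins of width 0.1. At
#' mutation-drift equilibrium the distribution is L-shaped (rare alleles
#' are the most numerous); a bottleneck shifts the mode away from the
#' lowest-frequency bin.
#'
#' @param g A [genotype_matrix()].
#' @return List with `verdict` (`"L-shaped"` or `"shifted"`) and `counts`
#'   (named vector of the ten bins).
#' @export
mode_shift <- function(g) {
  freqs <- unlist(lapply(seq_len(n_loci(g)), function(j) {
    copies <- gene_copies(g, j)
    if (length(copies)) as.numeric(table(copies)) / length(copies) else numeric(0)
  }))
  breaks <- seq(0, 1, by = 0.1)
  counts <- table(cut(freqs, breaks, include.lowest = TRUE))
  verdict <- if (counts[1] == max(counts)) "L-shaped" else "shifted"
  list(verdict = verdict, counts = counts)
}

#' Per-locus Garza-Williamson M-ratio
#'
#' `M = k / (r + 1)` with `k` the number of observed alleles and `r` the
#' allele-size range in repeat units; `M = 1` exactly when the alleles form
#' an unbroken ladder.
#'
#' @param g A [genotype_matrix()].
#' @return Data frame with `locus`, `k`, `r`, `M`, `monomorphic`.
#' @export
m_ratio <- function(g) {
  rows <- lapply(seq_len(n_loci(g)), function(j) {
    copies <- gene_copies(g, j)
    k <- length(unique(copies))
    r <- if (k) diff(range(copies)) else NA_integer_
    data.frame(locus = locus_names(g)[j], k = k, r = r,
               M = if (k) k / (r + 1) else NA_real_,
               monomorphic = k == 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' M-ratio bottleneck test with a simulation null
#'
#' The observed statistic is the mean per-locus M-ratio. The null
#' distribution comes from equilibrium coalescent samples under the
#' two-phase mutation model at the supplied `theta`, with matching per-locus
#' sample sizes; the p-value is the (add-one) fraction of simulated means at
#' or below the observed mean, since bottlenecks depress M.
#'
#' @param g A [genotype_matrix()].
#' @param params A [tpm_params()].
#' @param theta Mutation-scaled population size for the null simulations
#'   (required; a sensible choice is a moment estimate from heterozygosity).
#' @param n_sim Number of simulated datasets.
#' @param seed Optional RNG seed.
#' @return List with `per_locus` (from [m_ratio()]), `M_mean`, `p`, `theta`.
#' @export
m_ratio_test <- function(g, params = tpm_params(), theta, n_sim = 1000L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(theta > 0)
  per <- m_ratio(g)
  use <- !is.na(per$M)
  if (!any(use)) stop("no genotyped loci")
  m_obs <- mean(per$M[use])
  sizes <- vapply(which(use), function(j) length(gene_copies(g, j)), 0L)
  null_means <- vapply(seq_len(n_sim), function(b) {
    mean(vapply(sizes, function(n) {
      s <- sim_tpm_sample(n, theta, params)
      length(unique(s)) / (diff(range(s)) + 1)
    }, 0))
  }, 0)
  p <- (1 + sum(null_means <= m_obs + 1e-12)) / (n_sim + 1)
  list(per_locus = per, M_mean = m_obs, p = p, theta = theta,
       null_mean = mean(null_means))
}

#' Run all bottleneck screens
#'
#' Convenience wrapper running [het_excess_test()], [mode_shift()] and
#' [m_ratio_test()] and returning a combined report.
#'
#' @param g A [genotype_matrix()].
#' @param params A [tpm_params()].
#' @param theta Null-simulation theta for the M-ratio test.
#' @param n_sim Simulations per test.
#' @param seed Optional RNG seed.
#' @return List of class `"bottleneck_report"`.
#' @export
bottleneck_tests <- function(g, params = tpm_params(), theta,
                             n_sim = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  het <- het_excess_test(g, params, n_sim = n_sim)
  ms <- mode_shift(g)
  mr <- m_ratio_test(g, params, theta = theta, n_sim = n_sim)
  structure(list(het_excess = het, mode_shift = ms, m_ratio = mr),
            class = "bottleneck_report")
}

#' Write a bottleneck report as TSV and JSON
#'
#' The TSV holds the per-locus table (DH components and M-ratios); the JSON
#' additionally carries the test-level results.
#'
#' @param report A `"bottleneck_report"` from [bottleneck_tests()].
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_bottleneck_report <- function(report, tsv = NULL, json = NULL) {
  per <- merge(report$het_excess$per_locus, report$m_ratio$per_locus,
               by = "locus", all = TRUE)
  if (!is.null(tsv)) {
    utils::write.table(per, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(
      wilcoxon_p = report$het_excess$p_wilcoxon,
      n_loci_used = report$het_excess$n_loci_used,
      mode_shift = report$mode_shift$verdict,
      m_ratio_mean = report$m_ratio$M_mean,
      m_ratio_p = report$m_ratio$p,
      theta = report$m_ratio$theta,
      per_locus = per)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(report)
}

#' @export
print.bottleneck_report <- function(x, ...) {
  cat(sprintf("Wilcoxon heterozygote-excess (one-tailed): p = %.3f over %d loci\n",
              x$het_excess$p_wilcoxon, x$het_excess$n_loci_used))
  cat(sprintf("allele-frequency distribution: %s\n", x$mode_shift$verdict))
  cat(sprintf("mean M-ratio = %.3f (simulation p = %.3f at theta = %g)\n",
              x$m_ratio$M_mean, x$m_ratio$p, x$m_ratio$theta))
  invisible(x)
}
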