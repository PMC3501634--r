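#' Effective number of alleles
#'
#' `n_e = 1 / sum(p_i^2)`, the reciprocal of expected homozygosity.
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return The effective number of alleles, a real in `[1, k]`.
#' @export
effective_alleles <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  1 / sum(freqs^2)
}

#' Observed and expected heterozygosity at a locus
#'
#' `Ho` is the fraction of genotyped individuals carrying two different
#' alleles. `He` is Nei's unbiased expected heterozygosity,
#' `(2N / (2N - 1)) * (1 - sum(p_i^2))`.
#'
#' @param g A [genotype_matrix()].
#' @param locus Locus name or index.
#' @return Named numeric vector `c(Ho = , He = )`.
#' @export
heterozygosities <- function(g, locus) {
  j <- resolve_locus(g, locus)
  ok <- !is.na(g$a1[, j])
  if (!any(ok)) stop("no genotyped individuals at locus")
  ho <- mean(g$a1[ok, j] != g$a2[ok, j])
  p <- allele_frequencies(g, j)
  two_n <- 2 * sum(ok)
  he <- if (two_n > 1) (two_n / (two_n - 1)) * (1 - sum(p^2)) else 0
  c(Ho = ho, He = he)
}

# G statistic of a genotype sample against Hardy-Weinberg expectations.
# Classes are unordered genotypes; only classes with positive expectation
# (i.e. both alleles present) can be observed, and empty observed classes
# contribute 0 to G.
hwe_g_stat <- function(a1, a2) {
  n <- length(a1)
  geno <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")  # unordered pairs
  obs <- table(geno)
  copies <- c(a1, a2)
  p <- table(copies) / (2 * n)
  alleles <- as.integer(names(p))
  g <- 0
  for (cls in names(obs)) {
    ab <- as.integer(strsplit(cls, "/")[[1]])
    pa <- p[[as.character(ab[1])]]
    pb <- p[[as.character(ab[2])]]
    expc <- if (ab[1] == ab[2]) n * pa^2 else 2 * n * pa * pb
    g <- g + 2 * obs[[cls]] * log(obs[[cls]] / expc)
  }
  g
}

#' Hardy-Weinberg G-test with permutation p-value
#'
#' The G statistic is computed on unordered genotype classes against their
#' Hardy-Weinberg expectations; significance comes from shuffling the `2N`
#' gene copies among individuals (which preserves allele frequencies) and
#' recomputing G. The `(b + 1) / (n_perm + 1)` estimator avoids zero
#' p-values.
#'
#' @param g A [genotype_matrix()].
#' @param locus Locus name or index.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Optional RNG seed.
#' @return List with `G` and `p`.
#' @export
hwe_gtest <- function(g, locus, n_perm = 1000L, seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  j <- resolve_locus(g, locus)
  ok <- !is.na(g$a1[, j])
  a1 <- g$a1[ok, j]; a2 <- g$a2[ok, j]
  if (length(unique(c(a1, a2))) < 2L) stop("locus is monomorphic")
  g_obs <- hwe_g_stat(a1, a2)
  n <- length(a1)
  copies <- c(a1, a2)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(copies)
    gb <- hwe_g_stat(perm[seq_len(n)], perm[n + seq_len(n)])
    if (gb >= g_obs - 1e-12) hits <- hits + 1L
  }
  list(G = g_obs, p = (hits + 1) / (n_perm + 1))
}

#' Genotypic disequilibrium G-test for a pair of loci
#'
#' G is computed on the two-locus genotype contingency table over
#' individuals genotyped at both loci; the permutation null shuffles one
#' locus's genotypes among individuals, breaking any association while
#' preserving single-locus genotype frequencies.
#'
#' @param g A [genotype_matrix()].
#' @param locus_a,locus_b Locus names or indices.
#' @param n_perm Number of permutations (default 4500, the convention of
#'   FSTAT-style table-wide testing).
#' @param seed Optional RNG seed.
#' @return List with `G` and `p`.
#' @export
ld_gtest <- function(g, locus_a, locus_b, n_perm = 4500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ja <- resolve_locus(g, locus_a); jb <- resolve_locus(g, locus_b)
  ok <- !is.na(g$a1[, ja]) & !is.na(g$a1[, jb])
  if (!any(ok)) stop("no individuals genotyped at both loci")
  ga <- paste(g$a1[ok, ja], g$a2[ok, ja], sep = "/")
  gb <- paste(g$a1[ok, jb], g$a2[ok, jb], sep = "/")
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) {
    stop("both loci must be polymorphic among jointly genotyped individuals")
  }
  g_of <- function(x, y) {
    tab <- table(x, y)
    expc <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    keep <- tab > 0
    2 * sum(tab[keep] * log(tab[keep] / expc[keep]))
  }
  g_obs <- g_of(ga, gb)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (g_of(ga, sample(gb)) >= g_obs - 1e-12) hits <- hits + 1L
  }
  list(G = g_obs, p = (hits + 1) / (n_perm + 1))
}

# Weir & Cockerham (1984) within-population variance components for one
# sample at one locus. Returns c(b, c): b = between individuals within the
# sample, c = within individuals, summed over alleles. F_IS = 1 - c/(b+c).
wc_components <- function(a1, a2) {
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  bsum <- 0; csum <- 0
  for (al in alleles) {
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    h <- mean((a1 == al) != (a2 == al))  # heterozygous for this allele
    b <- n / (n - 1) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
    bsum <- bsum + b
    csum <- csum + h / 2
  }
  c(b = bsum, c = csum)
}

#' Weir & Cockerham F_IS with randomization test and bootstrap CI
#'
#' Per-locus F_IS uses the Weir & Cockerham (1984) variance-component
#' estimator for a single sample; the multilocus value is the weighted mean
#' obtained by summing components over loci, `1 - sum(c) / sum(b + c)`.
#' Per-locus significance comes from randomizing alleles among individuals
#' (two-sided); the multilocus confidence interval is a percentile bootstrap
#' over loci.
#'
#' @param g A [genotype_matrix()].
#' @param loci Optional subset of locus names; default all.
#' @param n_rand Randomizations per locus.
#' @param n_boot Bootstrap replicates over loci.
#' @param conf Confidence level for the bootstrap CI.
#' @param seed Optional RNG seed.
#' @return List with `per_locus` (data frame `locus`, `fis`, `p`),
#'   `weighted_mean`, and `ci` (length-2 vector), plus the components used.
#' @export
fis <- function(g, loci = NULL, n_rand = 1000L, n_boot = 1000L,
                conf = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loci)) loci <- locus_names(g)
  comp <- matrix(NA_real_, length(loci), 2,
                 dimnames = list(loci, c("b", "c")))
  fvec <- pvec <- rep(NA_real_, length(loci))
  for (k in seq_along(loci)) {
    j <- resolve_locus(g, loci[k])
    ok <- !is.na(g$a1[, j])
    a1 <- g$a1[ok, j]; a2 <- g$a2[ok, j]
    if (length(unique(c(a1, a2))) < 2L) {
      warning(sprintf("locus %s is monomorphic; skipped in F_IS", loci[k]))
      next
    }
    bc <- wc_components(a1, a2)
    comp[k, ] <- bc
    fvec[k] <- 1 - bc["c"] / sum(bc)
    n <- length(a1)
    copies <- c(a1, a2)
    hits <- 0L
    for (r in seq_len(n_rand)) {
      perm <- sample(copies)
      bcr <- wc_components(perm[seq_len(n)], perm[n + seq_len(n)])
      fr <- 1 - bcr["c"] / sum(bcr)
      if (abs(fr) >= abs(fvec[k]) - 1e-12) hits <- hits + 1L
    }
    pvec[k] <- (hits + 1) / (n_rand + 1)
  }
  used <- which(!is.na(fvec))
  if (length(used) == 0L) stop("no polymorphic loci for F_IS")
  wmean <- 1 - sum(comp[used, "c"]) / sum(comp[used, ])
  ci <- c(NA_real_, NA_real_)
  if (length(used) >= 2L) {
    boot <- replicate(n_boot, {
      idx <- sample(used, length(used), replace = TRUE)
      1 - sum(comp[idx, "c"]) / sum(comp[idx, ])
    })
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(a, 1 - a), na.rm = TRUE))
  }
  list(per_locus = data.frame(locus = loci, fis = fvec, p = pvec,
                              stringsAsFactors = FALSE),
       weighted_mean = wmean, ci = ci, components = comp)
}

#' Sequential Bonferroni (Holm) correction
#'
#' P-values are sorted ascending and rejected while
#' `p_(i) <= alpha / (m - i + 1)`; the first failure stops the procedure.
#' The boundary is inclusive. This rejects a superset of the classical
#' Bonferroni rejections.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed, never
#'   rejected and not counted in `m`).
#' @param alpha Family-wise level.
#' @return Logical vector of rejections, in the original order.
#' @export
sequential_bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  rej <- logical(length(pvals))
  m <- sum(ok)
  if (m == 0L) return(rej)
  ord <- order(pvals)
  ord <- ord[ok[ord]]
  for (i in seq_len(m)) {
    if (pvals[ord[i]] <= alpha / (m - i + 1)) rej[ord[i]] <- TRUE else break
  }
  rej
}

#' Per-locus summary table
#'
#' One row per locus with the standard microsatellite diversity statistics:
#' genotyped individuals (N), observed and effective allele numbers, observed
#' and Nei-unbiased expected heterozygosity, Weir-Cockerham F_IS, and a
#' permutation Hardy-Weinberg G-test p-value.
#'
#' @param g A [genotype_matrix()].
#' @param n_perm Permutations for the HWE test (0 skips it).
#' @param n_rand Randomizations for per-locus F_IS p-values.
#' @param seed Optional RNG seed.
#' @return A data frame with columns `locus`, `N`, `n_a`, `n_e`, `Ho`, `He`,
#'   `Fis`, `p_HWE`, plus attributes `fis_weighted_mean` and `fis_ci`.
#' @export
locus_summary <- function(g, n_perm = 1000L, n_rand = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(g)
  out <- data.frame(locus = locus_names(g), N = NA_integer_,
                    n_a = NA_integer_, n_e = NA_real_, Ho = NA_real_,
                    He = NA_real_, Fis = NA_real_, p_HWE = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(L)) {
    out$N[j] <- n_genotyped(g, j)
    if (out$N[j] == 0L) next
    p <- allele_frequencies(g, j)
    out$n_a[j] <- length(p)
    out$n_e[j] <- effective_alleles(p)
    hh <- heterozygosities(g, j)
    out$Ho[j] <- hh[["Ho"]]; out$He[j] <- hh[["He"]]
    if (out$n_a[j] >= 2L && n_perm >= 100L) {
      out$p_HWE[j] <- hwe_gtest(g, j, n_perm = n_perm)$p
    }
  }
  poly <- out$locus[!is.na(out$n_a) & out$n_a >= 2L]
  if (length(poly)) {
    f <- suppressWarnings(fis(g, loci = poly, n_rand = n_rand, n_boot = 500L))
    out$Fis[match(poly, out$locus)] <- f$per_locus$fis
    attr(out, "fis_weighted_mean") <- f$weighted_mean
    attr(out, "fis_ci") <- f$ci
  }
  out
}

#' Write the per-locus summary as TSV
#'
#' @param summary Output of [locus_summary()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
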