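# Per-locus ANOVA variance components of globally standardized allele sizes.
# Returns c(sa, sw) or NULL when the locus carries no between-group signal
# (monomorphic, or fewer than two usable groups).
rst_components <- function(sizes, grp) {
  ok <- !is.na(sizes)
  sizes <- sizes[ok]; grp <- grp[ok]
  if (length(sizes) < 4L) return(NULL)
  s <- stats::sd(sizes)
  if (s == 0) return(NULL)
  z <- (sizes - mean(sizes)) / s         # global standardization (RSTCALC)
  counts <- table(grp)
  if (length(counts) < 2L) return(NULL)
  d <- length(counts)
  N <- length(z)
  gm <- mean(z)
  means <- tapply(z, grp, mean)
  ssa <- sum(counts * (means[names(counts)] - gm)^2)
  ssw <- sum((z - means[grp])^2)
  msa <- ssa / (d - 1)
  msw <- ssw / (N - d)
  n0 <- (N - sum(counts^2) / N) / (d - 1)
  c(sa = (msa - msw) / n0, sw = msw)
}

rst_value <- function(g, grp_of_ind) {
  sa <- 0; sw <- 0; any_locus <- FALSE
  for (j in seq_len(n_loci(g))) {
    sizes <- c(g$a1[, j], g$a2[, j])
    grp <- rep(grp_of_ind, 2L)
    comp <- rst_components(sizes, grp)
    if (is.null(comp)) next
    any_locus <- TRUE
    sa <- sa + comp["sa"]; sw <- sw + comp["sw"]
  }
  if (!any_locus) return(NA_real_)
  unname(sa / (sa + sw))
}

#' Screen for population structure with R_ST
#'
#' Allele sizes are standardized per locus over the pooled sample (subtract
#' the global mean, divide by the global standard deviation), then
#' partitioned by a two-level analysis of variance into among-group and
#' within-group components summed over loci;
#' `R_ST = sigma2_among / (sigma2_among + sigma2_within)`. Negative
#' estimates are legitimate (sampling noise around zero differentiation) and
#' reported as-is. Significance comes from permuting individuals among
#' groups (both gene copies move together). Pairwise `R_ST` values for all
#' group pairs are tested the same way and corrected by sequential
#' Bonferroni. The scaled migration estimate `4Nm = (1 - R_ST) / R_ST` is
#' reported when `R_ST > 0` and flagged undefined otherwise.
#'
#' @param g A [genotype_matrix()] whose `groups` define the units.
#' @param n_perm Number of permutations.
#' @param alpha Level for the pairwise sequential Bonferroni.
#' @param seed Optional RNG seed.
#' @return An object of class `"structure_screen"`: a list with `rst`, `p`,
#'   `four_nm` (`NA` when undefined), `pairwise` (data frame), `groups`.
#' @export
rst_screen <- function(g, n_perm = 10000L, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- table(g$groups)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning(sprintf("excluding group(s) with <2 individuals: %s",
                    paste(small, collapse = ", ")))
    g <- subset_individuals(g, !(g$groups %in% small))
    counts <- table(g$groups)
  }
  grps <- names(counts)
  if (length(grps) < 2L) stop("need at least two groups of size >= 2")

  r_obs <- rst_value(g, g$groups)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (rst_value(g, sample(g$groups)) >= r_obs - 1e-12) hits <- hits + 1L
  }
  p_overall <- (hits + 1) / (n_perm + 1)

  pairs <- utils::combn(grps, 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   rst = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    sel <- g$groups %in% pairs[, k]
    gs <- subset_individuals(g, sel)
    r <- rst_value(gs, gs$groups)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (rst_value(gs, sample(gs$groups)) >= r - 1e-12) hits <- hits + 1L
    }
    pw$rst[k] <- r
    pw$p[k] <- (hits + 1) / (n_perm + 1)
  }
  pw$significant <- sequential_bonferroni(pw$p, alpha)

  structure(list(rst = r_obs, p = p_overall,
                 four_nm = if (!is.na(r_obs) && r_obs > 0)
                   (1 - r_obs) / r_obs else NA_real_,
                 pairwise = pw, groups = grps, n_perm = n_perm),
            class = "structure_screen")
}

#' @export
print.structure_screen <- function(x, ...) {
  cat(sprintf("R_ST over %d groups: %.4f (permutation p = %.4g)\n",
              length(x$groups), x$rst, x$p))
  if (is.na(x$four_nm)) {
    cat("4Nm: undefined (R_ST <= 0; consistent with panmixia)\n")
  } else {
    cat(sprintf("4Nm = (1 - R_ST)/R_ST = %.2f\n", x$four_nm))
  }
  nsig <- sum(x$pairwise$significant)
  cat(sprintf("pairwise comparisons: %d of %d significant after sequential Bonferroni\n",
              nsig, nrow(x$pairwise)))
  invisible(x)
}

#' Delta-mu-squared distances with neighbor-joining split
#'
#' `delta_mu2(A, B)` is the squared difference of mean allele sizes between
#' two groups, averaged over loci. With three or more groups a
#' neighbor-joining tree (Saitou & Nei, via \pkg{ape}) is built on the
#' distance matrix and the bipartition induced by its longest internal
#' branch is reported as the deepest split; ties are broken toward the
#' lexicographically smallest group set so the result is deterministic.
#'
#' @param g A [genotype_matrix()].
#' @return A list with `dist` (symmetric matrix), and, when at least three
#'   groups are present, `tree` (an \pkg{ape} `phylo`) and `split` (list of
#'   two character vectors of group names).
#' @export
delta_mu2_nj <- function(g) {
  grps <- sort(unique(g$groups))
  L <- n_loci(g)
  means <- matrix(NA_real_, length(grps), L, dimnames = list(grps, NULL))
  for (gi in seq_along(grps)) {
    sub <- subset_individuals(g, g$groups == grps[gi])
    for (j in seq_len(L)) {
      copies <- gene_copies(sub, j)
      if (length(copies)) means[gi, j] <- mean(copies)
    }
  }
  D <- matrix(0, length(grps), length(grps), dimnames = list(grps, grps))
  for (a in seq_along(grps)) for (b in seq_along(grps)) {
    if (a < b) {
      use <- !is.na(means[a, ]) & !is.na(means[b, ])
      if (!any(use)) stop("groups share no genotyped locus")
      D[a, b] <- D[b, a] <- mean((means[a, use] - means[b, use])^2)
    }
  }
  out <- list(dist = D)
  if (length(grps) >= 3L) {
    tree <- ape::nj(stats::as.dist(D))
    out$tree <- tree
    ntip <- length(tree$tip.label)
    internal <- tree$edge[, 1] > ntip & tree$edge[, 2] > ntip
    if (any(internal)) {
      lens <- tree$edge.length
      lens[!internal] <- -Inf
      best <- which(lens >= max(lens) - 1e-12)
      splits <- lapply(best, function(e) {
        below <- tips_below(tree, tree$edge[e, 2])
        side1 <- sort(tree$tip.label[below])
        side2 <- sort(setdiff(tree$tip.label, side1))
        if (paste(side1, collapse = ",") > paste(side2, collapse = ",")) {
          list(side2, side1)
        } else list(side1, side2)
      })
      keys <- vapply(splits, function(s) paste(s[[1]], collapse = ","), "")
      out$split <- splits[[order(keys)[1]]]
    }
  }
  out
}

#' Write a structure screen to disk
#'
#' The screen (overall and pairwise R_ST, permutation p-values, 4Nm) is
#' written as JSON; when a delta-mu-squared result with a tree is supplied,
#' the NJ tree is written in Newick alongside.
#'
#' @param screen A `"structure_screen"` from [rst_screen()].
#' @param json Output JSON path.
#' @param dmu Optional result of [delta_mu2_nj()].
#' @param newick Optional Newick output path for `dmu$tree`.
#' @return Invisibly, the screen.
#' @export
write_structure_screen <- function(screen, json, dmu = NULL, newick = NULL) {
  payload <- list(rst = screen$rst, p = screen$p, four_nm = screen$four_nm,
                  n_perm = screen$n_perm, groups = screen$groups,
                  pairwise = screen$pairwise)
  if (!is.null(dmu)) {
    payload$delta_mu2 <- as.data.frame(as.table(dmu$dist),
                                       stringsAsFactors = FALSE)
    if (!is.null(dmu$split)) {
      payload$deepest_split <- dmu$split
    }
  }
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (!is.null(newick) && !is.null(dmu$tree)) {
    ape::write.tree(dmu$tree, file = newick)
  }
  invisible(screen)
}

# tip indices in the clade below an internal node of an ape phylo
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) tips <- c(tips, v) else {
      stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
    }
  }
  tips
}
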