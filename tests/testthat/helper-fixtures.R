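# Small builders used across the suite; everything is generated in code.

# genotype matrix from explicit allele pair rows: ab is a 2-column matrix per
# locus (one row per individual), NA rows are missing calls
make_g <- function(..., groups = NULL, repeat_min = 1L, repeat_max = 35L) {
  pairs <- list(...)
  n <- nrow(pairs[[1]])
  a1 <- sapply(pairs, function(p) p[, 1])
  a2 <- sapply(pairs, function(p) p[, 2])
  a1 <- matrix(as.integer(a1), n); a2 <- matrix(as.integer(a2), n)
  if (is.null(groups)) groups <- rep("a", n)
  loci <- lapply(seq_along(pairs), function(j) {
    locus(paste0("L", j), repeat_min = repeat_min, repeat_max = repeat_max)
  })
  genotype_matrix(a1, a2, groups, loci)
}

# genotype matrix from per-locus gene-copy vectors on a free lattice (used
# with the unbounded two-phase-model simulator); copies are shifted to >= 1
g_from_copies <- function(copies_list, groups = NULL) {
  n <- length(copies_list[[1]]) %/% 2L
  L <- length(copies_list)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  loci <- vector("list", L)
  for (j in seq_len(L)) {
    v <- copies_list[[j]]
    v <- as.integer(v - min(v) + 1L)
    a1[, j] <- v[2L * seq_len(n) - 1L]
    a2[, j] <- v[2L * seq_len(n)]
    hi <- max(v, 2L)
    loci[[j]] <- locus(paste0("L", j), repeat_min = 1L, repeat_max = hi,
                       global_cap = hi)
  }
  if (is.null(groups)) groups <- rep("a", n)
  genotype_matrix(a1, a2, groups, loci)
}

# manual genealogy from parent/children/time vectors
make_tree <- function(n_tips, parent, children, time) {
  structure(list(n_tips = as.integer(n_tips), parent = as.integer(parent),
                 children = children, time = time), class = "genealogy")
}

# balanced 3-tip tree: tips 1,2 join at node 4 (t1), then 3 at node 5 (t2)
tree3 <- function(t1 = 0.3, t2 = 0.8) {
  ch <- matrix(NA_integer_, 5, 2)
  ch[4, ] <- c(1L, 2L); ch[5, ] <- c(4L, 3L)
  make_tree(3, c(4L, 4L, 5L, 5L, 0L), ch, c(0, 0, 0, t1, t2))
}

# brute-force likelihood of tip states on a 3-tip tree by exhaustive
# summation over internal states, with dense matrix exponentials
brute_force_3leaf <- function(tips, tree, Q) {
  states <- as.integer(rownames(Q))
  pi <- unname(stationary_distribution(Q))
  P <- function(t) as.matrix(Matrix::expm(Matrix::Matrix(unclass(Q) * t)))
  root <- which(tree$parent == 0L)
  other <- setdiff(which(!is.na(tree$children[, 1])), root)
  tot <- 0
  for (ri in seq_along(states)) for (oi in seq_along(states)) {
    st <- numeric(5)
    st[root] <- states[ri]; st[other] <- states[oi]
    p <- pi[ri]
    for (v in c(root, other)) for (ch in tree$children[v, ]) {
      tgt <- if (ch <= 3) tips[ch] else st[ch]
      Pm <- P(tree$time[v] - tree$time[ch])
      p <- p * Pm[match(st[v], states), match(tgt, states)]
    }
    tot <- tot + p
  }
  log(tot)
}
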