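#' Demography functions
#'
#' A demography is the effective-size trajectory `theta(t)` in
#' mutation-scaled units, with `t` measured backwards from the present.
#' Three parametric kinds are supported: constant, exponential
#' (`theta(t) = theta0 * exp(-growth * t)`, so positive `growth` means the
#' population has been growing towards the present), and piecewise constant
#' with change points.
#'
#' @param theta,theta0 Positive size parameter(s).
#' @param growth Exponential growth rate per unit time.
#' @param times Strictly increasing positive change points.
#' @param thetas Segment sizes, one more than `times`; `thetas[1]` applies
#'   on `[0, times[1])`.
#' @return An object of class `"demography"`.
#' @name demography
NULL

#' @rdname demography
#' @export
constant_demography <- function(theta) {
  stopifnot(theta > 0)
  structure(list(kind = "CONSTANT", theta = theta), class = "demography")
}

#' @rdname demography
#' @export
exponential_demography <- function(theta0, growth) {
  stopifnot(theta0 > 0)
  structure(list(kind = "EXPONENTIAL", theta0 = theta0, growth = growth),
            class = "demography")
}

#' @rdname demography
#' @export
piecewise_demography <- function(times, thetas) {
  times <- as.numeric(times)
  if (length(thetas) != length(times) + 1L) {
    stop("need one more theta than change points")
  }
  if (length(times) && (any(diff(times) <= 0) || any(times <= 0))) {
    stop("change points must be strictly increasing and positive")
  }
  if (any(thetas <= 0)) stop("thetas must be positive")
  structure(list(kind = "PIECEWISE", times = times, thetas = as.numeric(thetas)),
            class = "demography")
}

#' Evaluate theta(t)
#' @param dem A [demography] object.
#' @param t Time(s) before present, >= 0.
#' @return Numeric vector of sizes.
#' @export
theta_at <- function(dem, t) {
  switch(dem$kind,
         CONSTANT = rep(dem$theta, length(t)),
         EXPONENTIAL = dem$theta0 * exp(-dem$growth * t),
         PIECEWISE = dem$thetas[findInterval(t, dem$times) + 1L])
}

# integral of 1/theta(t) dt over [t0, t1], exact for every kind
intensity_integral <- function(dem, t0, t1) {
  if (t1 < t0) stop("t1 must be >= t0")
  switch(dem$kind,
    CONSTANT = (t1 - t0) / dem$theta,
    EXPONENTIAL = {
      g <- dem$growth
      if (abs(g) < 1e-12) (t1 - t0) / dem$theta0
      else (exp(g * t1) - exp(g * t0)) / (dem$theta0 * g)
    },
    PIECEWISE = {
      brk <- c(0, dem$times, Inf)
      tot <- 0
      for (s in seq_along(dem$thetas)) {
        lo <- max(t0, brk[s]); hi <- min(t1, brk[s + 1L])
        if (hi > lo) tot <- tot + (hi - lo) / dem$thetas[s]
      }
      tot
    })
}

# Waiting time from t0 until cumulative pair intensity reaches e/(k choose 2):
# solves integral_{t0}^{t0+dt} C(k,2)/theta(t) dt = e. Exact inversion for
# CONSTANT and EXPONENTIAL, segment-walk for PIECEWISE. Returns Inf when the
# target is unreachable (possible under strong decline into the past).
coalescent_waiting_time <- function(dem, t0, k, e) {
  ck2 <- k * (k - 1) / 2
  target <- e / ck2
  switch(dem$kind,
    CONSTANT = target * dem$theta,
    EXPONENTIAL = {
      g <- dem$growth
      if (abs(g) < 1e-12) return(target * dem$theta0)
      arg <- exp(g * t0) + target * dem$theta0 * g
      if (arg <= 0) return(Inf)
      log(arg) / g - t0
    },
    PIECEWISE = {
      brk <- c(0, dem$times, Inf)
      s <- findInterval(t0, dem$times) + 1L
      t <- t0
      remaining <- target
      repeat {
        seg_end <- brk[s + 1L]
        cap <- (seg_end - t) / dem$thetas[s]
        if (remaining <= cap) return(t + remaining * dem$thetas[s] - t0)
        remaining <- remaining - cap
        t <- seg_end
        s <- s + 1L
      }
    })
}

#' Simulate a coalescent genealogy
#'
#' Draws a rooted binary genealogy for `n` gene copies under the
#' time-inhomogeneous Kingman coalescent with pairwise rate
#' `choose(k, 2) / theta(t)`, using exact time rescaling.
#'
#' @param n Number of tips (>= 2).
#' @param dem A [demography] object.
#' @param seed Optional RNG seed.
#' @return An object of class `"genealogy"`: a list with `n_tips`, `parent`
#'   (0 for the root), `children` (2-column matrix, `NA` rows for tips) and
#'   `time` (0 for tips, increasing root-ward). Node ids `1..n` are tips.
#' @export
simulate_genealogy <- function(n, dem, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  stopifnot(n >= 2L)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  children <- matrix(NA_integer_, n_nodes, 2L)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    dt <- coalescent_waiting_time(dem, t, k, stats::rexp(1))
    if (!is.finite(dt)) stop("coalescence unreachable under this demography")
    t <- t + dt
    pair <- sample(active, 2L)
    parent[pair] <- nxt
    children[nxt, ] <- pair
    time[nxt] <- t
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  structure(list(n_tips = n, parent = parent, children = children,
                 time = time), class = "genealogy")
}

genealogy_root <- function(tree) which(tree$parent == 0L)

#' Root height of a genealogy
#' @param tree A `"genealogy"`.
#' @return The time of the root node.
#' @export
root_height <- function(tree) tree$time[genealogy_root(tree)]

#' Convert a genealogy to an ape "phylo"
#' @param tree A `"genealogy"`.
#' @return An \pkg{ape} `phylo` with branch lengths in mutation units.
#' @export
genealogy_to_phylo <- function(tree) {
  n <- tree$n_tips
  internal <- which(!is.na(tree$children[, 1]))
  # ape wants the root to be node n+1
  remap <- integer(length(tree$parent))
  remap[seq_len(n)] <- seq_len(n)
  root <- genealogy_root(tree)
  ord <- c(root, setdiff(internal, root))
  remap[ord] <- n + seq_along(ord)
  edge <- cbind(remap[tree$parent[tree$parent != 0L]],
                remap[which(tree$parent != 0L)])
  len <- tree$time[tree$parent[tree$parent != 0L]] -
    tree$time[which(tree$parent != 0L)]
  phy <- list(edge = edge, edge.length = len,
              tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Write genealogies to a Newick file
#' @param trees A `"genealogy"` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genealogy_newick <- function(trees, path) {
  if (inherits(trees, "genealogy")) trees <- list(trees)
  phys <- lapply(trees, genealogy_to_phylo)
  class(phys) <- "multiPhylo"
  ape::write.tree(phys, file = path)
  invisible(path)
}

#' Evolve a microsatellite along a genealogy
#'
#' The root state is drawn from the mutation model's stationary
#' distribution; states then evolve along each branch by direct (Gillespie)
#' simulation of the continuous-time Markov chain.
#'
#' @param tree A `"genealogy"`.
#' @param model A [mutation_model()] (or a prebuilt rate matrix via `Q`).
#' @param Q Optional rate matrix, to avoid rebuilding per call.
#' @param rate_modifier Multiplier on the chain's time scale for this locus.
#' @param seed Optional RNG seed.
#' @return Integer vector of repeat counts, one per tip.
#' @export
evolve_microsatellite <- function(tree, model, Q = NULL, rate_modifier = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(Q)) Q <- build_rate_matrix(model)
  states <- as.integer(rownames(Q))
  pi <- stationary_distribution(Q)
  root <- genealogy_root(tree)
  node_state <- integer(length(tree$parent))
  node_state[root] <- sample(states, 1L, prob = pi)
  # depth-first from the root
  stack <- root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree$children[v, ]
    if (is.na(kids[1])) next
    for (ch in kids) {
      len <- (tree$time[v] - tree$time[ch]) * rate_modifier
      s <- node_state[v]
      t_left <- len
      repeat {
        idx <- match(s, states)
        rate <- -Q[idx, idx]
        if (rate <= 0) break
        w <- stats::rexp(1, rate)
        if (w > t_left) break
        t_left <- t_left - w
        probs <- Q[idx, ]; probs[idx] <- 0
        s <- states[sample.int(length(states), 1L, prob = probs)]
      }
      node_state[ch] <- s
      stack <- c(stack, ch)
    }
  }
  node_state[seq_len(tree$n_tips)]
}

# Structured (n-island) coalescent for gene copies with deme labels, constant
# per-deme size theta_deme and scaled migration M (= 4Nm): per-lineage
# migration rate M / (2 * theta_deme) in mutation-scaled time. Returns a
# genealogy for the labelled copies.
simulate_structured_genealogy <- function(deme_of_tip, theta_deme, M) {
  n <- length(deme_of_tip)
  stopifnot(n >= 2L, M > 0, theta_deme > 0)
  demes <- sort(unique(deme_of_tip))
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  children <- matrix(NA_integer_, n_nodes, 2L)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  loc <- deme_of_tip
  t <- 0
  nxt <- n + 1L
  mig_rate_per_lineage <- M / (2 * theta_deme)
  while (length(active) > 1L) {
    k_by <- table(factor(loc[active], levels = demes))
    coal_rates <- as.numeric(k_by * (k_by - 1) / 2) / theta_deme
    mig_total <- length(active) * mig_rate_per_lineage * (length(demes) > 1L)
    total <- sum(coal_rates) + mig_total
    t <- t + stats::rexp(1, total)
    if (stats::runif(1) < mig_total / total) {
      lin <- sample(active, 1L)
      loc[lin] <- sample(setdiff(demes, loc[lin]), 1L)
    } else {
      deme <- sample(demes, 1L, prob = coal_rates / sum(coal_rates))
      here <- active[loc[active] == deme]
      pair <- sample(here, 2L)
      parent[pair] <- nxt
      children[nxt, ] <- pair
      time[nxt] <- t
      loc <- c(loc, deme)                # the merged lineage lives in `deme`
      active <- c(setdiff(active, pair), nxt)
      nxt <- nxt + 1L
    }
  }
  structure(list(n_tips = n, parent = parent, children = children,
                 time = time), class = "genealogy")
}

#' Simulate a synthetic microsatellite dataset
#'
#' The synthetic-data engine: per locus, a coalescent genealogy for the
#' `2 * n_ind` gene copies (panmictic, or an n-island structured coalescent
#' with symmetric scaled migration `M = 4Nm` when several groups are
#' requested), microsatellite evolution along it under the locus's mutation
#' model, random pairing of gene copies into diploids within groups, and
#' missing-call injection. The defaults emulate the red colobus study
#' conditions: 85 diploid individuals in 6 groups connected by high gene
#' flow, 10 loci on the repeat lattice `[1, 35]` with 3-14 alleles per
#' locus.
#'
#' @param n_ind Number of diploid individuals (overridden by
#'   `group_sizes` when given).
#' @param n_loci_sim Number of loci.
#' @param model A [mutation_model()] or list of one per locus (default: the
#'   equal-rate unbiased single-step model `EU1`).
#' @param dem A [demography] object (default constant `theta = 4`; together
#'   with the default model this reproduces the emulated study's per-locus
#'   allele-count spread of 3-14 and heterozygosities near 0.7).
#' @param group_sizes Named integer vector of individuals per group
#'   (default: the study's six social groups, 32/32/5/5/5/6).
#' @param migration Scaled migration `4Nm` between demes (default 100, well
#'   inside the high-gene-flow regime); only used with > 1 group. Structured
#'   simulation requires a constant demography.
#' @param missing_rate Per-call missing probability (default 0.028, the
#'   study's genotyping completeness).
#' @param seed Optional RNG seed.
#' @return A [genotype_matrix()].
#' @export
simulate_dataset <- function(n_ind = 85L, n_loci_sim = 10L,
                             model = NULL, dem = NULL,
                             group_sizes = NULL, migration = 100,
                             missing_rate = 0.028, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(group_sizes)) {
    group_sizes <- if (n_ind == 85L) {
      c(LargeMikana = 32L, SmallCamp = 32L, Dura = 5L, K30 = 5L,
        Mainaro = 5L, Sebatoli = 6L)
    } else c(pop1 = as.integer(n_ind))
  }
  n_ind <- sum(group_sizes)
  stopifnot(n_ind >= 2L)
  if (is.null(dem)) dem <- constant_demography(4)
  if (is.null(model)) model <- mutation_model_by_name("EU1")
  models <- if (inherits(model, "mutation_model")) {
    rep(list(model), n_loci_sim)
  } else model
  stopifnot(length(models) == n_loci_sim)
  d <- length(group_sizes)
  if (d > 1L) {
    if (dem$kind != "CONSTANT") {
      stop("structured simulation supports constant demography only")
    }
    if (is.null(migration) || migration <= 0) {
      stop("migration must be positive with more than one group")
    }
  }
  groups <- rep(names(group_sizes), group_sizes)
  deme_of_ind <- rep(seq_len(d), group_sizes)
  a1 <- a2 <- matrix(NA_integer_, n_ind, n_loci_sim)
  loci <- vector("list", n_loci_sim)
  for (j in seq_len(n_loci_sim)) {
    mo <- models[[j]]
    Q <- build_rate_matrix(mo)
    if (d == 1L) {
      tree <- simulate_genealogy(2L * n_ind, dem)
    } else {
      tree <- simulate_structured_genealogy(rep(deme_of_ind, each = 2L),
                                            theta_deme = dem$theta / d,
                                            M = migration)
    }
    tips <- evolve_microsatellite(tree, mo, Q = Q)
    # pair copies into diploids within demes: tips 2i-1, 2i belong to ind i,
    # but shuffle copy assignment within each deme for random mating
    for (dm in seq_len(d)) {
      inds <- which(deme_of_ind == dm)
      copy_idx <- as.vector(rbind(2L * inds - 1L, 2L * inds))
      perm <- sample(copy_idx)
      for (ii in seq_along(inds)) {
        a1[inds[ii], j] <- tips[perm[2L * ii - 1L]]
        a2[inds[ii], j] <- tips[perm[2L * ii]]
      }
    }
    loci[[j]] <- locus(paste0("L", j), repeat_min = mo$i_min,
                       repeat_max = mo$i_max,
                       global_cap = max(35L, mo$i_max))
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_ind * n_loci_sim) < missing_rate,
                   n_ind, n_loci_sim)
    # keep at least one genotyped individual per locus
    for (j in seq_len(n_loci_sim)) if (all(miss[, j])) miss[1L, j] <- FALSE
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  genotype_matrix(a1, a2, groups, loci)
}
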