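#' Back-transform log10-scale posterior summaries to the linear scale
#'
#' Each value maps through `x -> 10^x`; ordering is preserved.
#'
#' @param mean Posterior mean on the log10 scale.
#' @param hpd Length-2 vector of HPD bounds on the log10 scale.
#' @return Named list `mean`, `lower`, `upper` on the linear scale.
#' @export
transform_log10_summaries <- function(mean, hpd) {
  stopifnot(is.finite(mean), length(hpd) == 2L, all(is.finite(hpd)))
  list(mean = 10^mean, lower = 10^min(hpd), upper = 10^max(hpd))
}

#' Convert mutation-scaled quantities to natural units
#'
#' Genealogy heights are in expected mutations per lineage, so
#' `years = (height / mu) * generation_time`; the mutation-scaled size
#' converts as `Ne = theta / (4 mu)` for diploids. Halving `mu` doubles
#' both outputs: switching `mu` from 5e-4 to 1e-4 multiplies times and
#' sizes by exactly five.
#'
#' @param height Genealogy height (mutation units).
#' @param theta Mutation-scaled population size.
#' @param mu Mutation rate per locus per generation (default `5e-4`).
#' @param generation_time Generation time in years (default 5).
#' @return Named list `years`, `Ne`.
#' @export
scale_to_natural_units <- function(height, theta, mu = 5e-4,
                                   generation_time = 5) {
  stopifnot(height > 0 || height == 0, theta > 0, mu > 0, generation_time > 0)
  list(years = (height / mu) * generation_time, Ne = theta / (4 * mu))
}

#' Convert generations to years
#' @param gens Number of generations (>= 0).
#' @param generation_time Years per generation.
#' @return Years.
#' @export
generations_to_years <- function(gens, generation_time) {
  stopifnot(gens >= 0, generation_time > 0)
  gens * generation_time
}

#' Relative model probabilities from log marginal likelihoods
#'
#' Max-shifted softmax: `p_i = exp(lnml_i - m) / sum(exp(lnml - m))`.
#' Invariant to adding a constant to every ln mL.
#'
#' @param lnmls Named numeric vector of log marginal likelihoods.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
model_probabilities <- function(lnmls) {
  stopifnot(length(lnmls) >= 1L)
  w <- exp(lnmls - max(lnmls))
  w / sum(w)
}

#' Effective-to-census population size ratio
#' @param Ne Effective size.
#' @param Nc Census size (> 0).
#' @return `Ne / Nc`.
#' @export
ne_nc_ratio <- function(Ne, Nc) {
  stopifnot(Nc > 0)
  Ne / Nc
}

#' Build a run configuration
#'
#' @param input Optional path to a GenePop (`.gen`) or CSV genotype file;
#'   `NULL` simulates the default synthetic dataset instead.
#' @param mu Mutation rate per locus per generation.
#' @param mu_alt Alternative rate also reported in the conversions stage.
#' @param generation_time Years per generation.
#' @param Nc Optional census size for the Ne/Nc ratio.
#' @param stages Character vector of stages to run, a subset of
#'   `c("qc", "sumstats", "structure", "bottleneck", "infer", "compare",
#'   "conversions")`.
#' @param models Mutation-model names for the inference stage.
#' @param seed RNG seed for the whole pipeline.
#' @param n_perm Permutations for the permutation tests.
#' @param n_sim Simulations for the bottleneck nulls.
#' @param mcmc_iter,mcmc_burnin Chain settings for the inference stage.
#' @param sim Named list overriding [simulate_dataset()] arguments when
#'   simulating.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(input = NULL, mu = 5e-4, mu_alt = 1e-4,
                       generation_time = 5, Nc = NULL,
                       stages = c("qc", "sumstats", "structure",
                                  "bottleneck", "infer", "compare",
                                  "conversions"),
                       models = c("PU2", "EU1"), seed = 1L,
                       n_perm = 1000L, n_sim = 200L,
                       mcmc_iter = 1500L, mcmc_burnin = 0.1,
                       sim = list()) {
  stopifnot(mu > 0, generation_time > 0)
  structure(list(input = input, mu = mu, mu_alt = mu_alt,
                 generation_time = generation_time, Nc = Nc,
                 stages = stages, models = models, seed = as.integer(seed),
                 n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
                 mcmc_iter = as.integer(mcmc_iter),
                 mcmc_burnin = mcmc_burnin, sim = sim),
            class = "run_config")
}

#' Read a YAML run configuration
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: locus QC, summary statistics, structure screening,
#' bottleneck tests, per-model skyline MCMC, model comparison, and
#' natural-unit conversions. A failing optional stage is logged and the
#' remaining stages proceed. All randomness derives from `cfg$seed`, so a
#' rerun with the same configuration reproduces every table.
#'
#' @param cfg A [run_config()].
#' @return List of class `"msatdemog_report"` with one element per stage
#'   plus a `provenance` block (config hash, seed, package version).
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  report <- list(provenance = list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    package = as.character(utils::packageVersion("msatdemog")),
    timestamp_free = TRUE))
  log <- character(0)
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  g <- if (is.null(cfg$input)) {
    say("input: synthetic dataset (default study-shaped preset)")
    do.call(simulate_dataset, cfg$sim)
  } else if (grepl("\\.csv$", cfg$input, ignore.case = TRUE)) {
    say("input: CSV %s", cfg$input)
    read_genotype_csv(cfg$input)
  } else {
    say("input: GenePop %s", cfg$input)
    read_genepop(cfg$input)
  }
  report$data <- list(n_individuals = n_individuals(g), n_loci = n_loci(g),
                      groups = table(g$groups))

  run_stage <- function(name, expr) {
    if (!(name %in% cfg$stages)) {
      say("stage %s: skipped", name)
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
  }

  report$qc <- run_stage("qc", screen_null_alleles(g, n_perm = cfg$n_perm))
  if (!is.null(report$qc)) {
    drop <- report$qc$locus[report$qc$exclude]
    if (length(drop) && length(drop) < n_loci(g)) {
      say("qc: excluding %s", paste(drop, collapse = ", "))
      g <- exclude_loci(g, drop)
    }
  }
  report$sumstats <- run_stage("sumstats", {
    locus_summary(g, n_perm = cfg$n_perm)
  })
  report$structure <- run_stage("structure", {
    list(rst = rst_screen(g, n_perm = min(cfg$n_perm, 2000L)),
         delta_mu2 = delta_mu2_nj(g))
  })
  report$bottleneck <- run_stage("bottleneck", {
    theta_hat <- mean(vapply(seq_len(n_loci(g)), function(j) {
      stats::var(as.numeric(gene_copies(g, j)))
    }, 0))
    bottleneck_tests(g, tpm_params(), theta = theta_hat, n_sim = cfg$n_sim)
  })
  report$infer <- run_stage("infer", {
    posts <- lapply(cfg$models, function(mn) {
      run_mcmc(g, mutation_model_by_name(mn), dem_kind = "SKYLINE",
               n_iter = cfg$mcmc_iter, burnin = cfg$mcmc_burnin,
               ess_warn = 0)
    })
    names(posts) <- cfg$models
    lapply(posts, function(p) list(
      summary = summarize_posterior(p),
      lnml = estimate_lnml(p, "HARMONIC_MEAN"),
      samples = p$samples))
  })
  report$compare <- run_stage("compare", {
    if (is.null(report$infer)) stop("inference stage did not run")
    lnmls <- vapply(report$infer, function(x) x$lnml$lnml, 0)
    list(ranking = compare_models(lnmls),
         probabilities = model_probabilities(lnmls))
  })
  report$conversions <- run_stage("conversions", {
    if (is.null(report$infer)) stop("inference stage did not run")
    best <- report$infer[[1L]]
    tc <- best$summary$tcoal[["mean"]]
    th <- mean(best$samples$theta0)
    primary <- scale_to_natural_units(tc, th, cfg$mu, cfg$generation_time)
    alt <- scale_to_natural_units(tc, th, cfg$mu_alt, cfg$generation_time)
    out <- list(mu = cfg$mu, mu_alt = cfg$mu_alt,
                tcoal_years = primary$years, Ne = primary$Ne,
                tcoal_years_alt = alt$years, Ne_alt = alt$Ne)
    if (!is.null(cfg$Nc)) out$ne_nc <- ne_nc_ratio(primary$Ne, cfg$Nc)
    out
  })
  report$log <- log
  class(report) <- "msatdemog_report"
  report
}

#' @export
print.msatdemog_report <- function(x, ...) {
  cat("msatdemog pipeline report\n")
  cat(sprintf("data: %d individuals x %d loci\n",
              x$data$n_individuals, x$data$n_loci))
  for (line in x$log) cat(" -", line, "\n")
  if (!is.null(x$structure)) {
    cat(sprintf("R_ST = %.4f (p = %.3f)\n",
                x$structure$rst$rst, x$structure$rst$p))
  }
  if (!is.null(x$bottleneck)) print(x$bottleneck)
  if (!is.null(x$compare)) {
    best <- x$compare$ranking$model[1]
    cat(sprintf("best model: %s (relative probability %.3f)\n", best,
                x$compare$probabilities[[best]]))
  }
  if (!is.null(x$conversions)) {
    cat(sprintf("T_COAL ~ %.0f years, Ne ~ %.0f (mu = %g); x%g under mu = %g\n",
                x$conversions$tcoal_years, x$conversions$Ne, x$conversions$mu,
                x$conversions$mu / x$conversions$mu_alt, x$conversions$mu_alt))
  }
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Writes machine-readable JSON (full precision) plus TSV tables per stage
#' and a short Markdown summary (years rounded to integers, probabilities
#' to 3 decimals).
#'
#' @param report A `"msatdemog_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- rapply(unclass(report), f = function(x) x, how = "replace")
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  if (!is.null(report$sumstats)) {
    write_summary_tsv(report$sumstats, file.path(dir, "sumstats.tsv"))
  }
  if (!is.null(report$qc)) {
    write_qc_report(report$qc, tsv = file.path(dir, "qc.tsv"))
  }
  if (!is.null(report$compare)) {
    utils::write.table(report$compare$ranking,
                       file.path(dir, "model_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  md <- c("# Pipeline summary", "", report$log, "")
  if (!is.null(report$conversions)) {
    md <- c(md, sprintf("- T_COAL: %d years (mu = %g)",
                        round(report$conversions$tcoal_years),
                        report$conversions$mu),
            sprintf("- Ne: %d", round(report$conversions$Ne)))
  }
  if (!is.null(report$compare)) {
    p <- report$compare$probabilities
    md <- c(md, sprintf("- model probabilities: %s",
                        paste(sprintf("%s=%.3f", names(p), p), collapse = ", ")))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
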