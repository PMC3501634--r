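---
title: "Inferring historical demography from microsatellites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring historical demography from microsatellites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msatdemog` reconstructs the demographic history of a single population from
diploid microsatellite genotypes. The package grew out of a classic
conservation-genetics question — has the Kibale National Park red colobus
population been stable through the Late Pleistocene? — and implements the
full analysis chain such a study needs: data quality control, per-locus
diversity statistics, a screen for hidden population structure, tests for
recent bottlenecks, and multi-locus Bayesian inference of the effective
population size through time under a family of twelve microsatellite
mutation models compared by Bayes factors.

This vignette explains the models, their assumptions, and the design
decisions behind the implementation. It states no empirical result that the
package's tests do not themselves compute.

## Data model

Alleles are **repeat counts** on a bounded integer lattice, not fragment
lengths: a `locus` declares its motif length, lattice bounds
`[repeat_min, repeat_max]` and the affine code-to-repeat mapping used when
reading genotyping output. The default global cap of 35 repeats comfortably
exceeds the longest alleles seen in primate data of this kind (33 repeats in
the emulated study). Diploid calls are unordered pairs; phasing is never
assumed, and a missing call removes both gene copies of that individual at
that locus.

Locus-level QC estimates the null-allele frequency with the Brookfield
estimator `(He - Ho)/(1 + He)` and flags loci whose homozygote excess
survives a one-sided randomization test after sequential Bonferroni
correction. The estimator was chosen for its closed form (hence direct
testability); the full heuristic battery of electropherogram-level checkers
is out of scope. Flagged loci are recommended for exclusion, mirroring the
usual practice of dropping a misbehaving locus before demographic analysis.

## Summary statistics and their tests

Expected heterozygosity uses Nei's unbiased correction
`(2N/(2N-1)) (1 - sum p^2)`, the convention of the classic table-generating
programs, so that summary tables are well defined. `F_IS` is the
Weir & Cockerham (1984) variance-component estimator; the multilocus value
is the "weighted mean" obtained by summing components over loci rather than
averaging ratios, with a percentile bootstrap over loci for its confidence
interval. Hardy-Weinberg and genotypic-disequilibrium G-tests use
permutation nulls (shuffling gene copies among individuals, and one locus's
genotypes among individuals, respectively) rather than asymptotic
chi-squared tail areas, because microsatellite genotype tables are sparse;
every permutation p-value uses the add-one estimator `(b + 1)/(n + 1)` and
so can never be exactly zero. Multiple testing uses the sequential
Bonferroni (Holm) ladder with an inclusive boundary.

## Structure screening

`R_ST` follows the globally-standardized allele-size ANOVA: sizes are
standardized per locus over the pooled sample, variance components are
summed across loci, and significance comes from permuting individuals among
groups (both gene copies travel together, since the individual is the
sampling unit). Negative estimates are reported as-is — they are the
expected behaviour of an unbiased component ratio near zero
differentiation. `4Nm` is reported as `(1 - R_ST)/R_ST` only when
`R_ST > 0`; for non-positive estimates it is flagged undefined, since no
simple transform of a negative `R_ST` yields a meaningful migrant number.
The between-group distance is `delta-mu-squared` (squared difference of
mean allele sizes, averaged over loci), summarized by a neighbor-joining
tree whose longest internal branch defines the deepest split; ties are
broken toward the lexicographically smallest group set so results are
reproducible.

## Bottleneck tests

The two-phase mutation model (TPM) mixes single-repeat steps (probability
`p_single`) with geometric multi-repeat steps. Both published
parameterizations are accepted: stating the geometric law's **variance**
(the BOTTLENECK convention, recommended value 12, which maps to success
parameter `q = 1/4`) or its **mean** (the M_P_VAL convention, recommended
value 2.8, `q = 1/2.8`); defaults follow the latter with `p_single = 0.88`.

The heterozygote-excess test simulates, for each locus, equilibrium
coalescent samples under the TPM **conditioned on the observed allele
count** k: the simulation theta is tuned by bisection until k is typical,
then exact-k samples are kept by rejection. The standardized excess
`DH = (He_obs - mean He_eq)/sd(He_eq)` is combined across loci by a
one-tailed Wilcoxon signed-rank test. Equilibrium samples come from
coalescent simulation (mutations Poisson on branches) rather than forward
simulation — orders of magnitude faster at identical stationary behaviour.
The mode-shift descriptor bins pooled allele frequencies into ten classes
of width 0.1 and calls the distribution L-shaped when the rarest class
holds the most alleles.

The Garza-Williamson ratio is `M = k/(r + 1)` per locus (`r` = allele-size
range); its null distribution is the mean `M` over loci of equilibrium TPM
simulations at a user-supplied theta with matching sample sizes. Theta is a
required input because the observed data do not identify it separately for
this test; the pipeline uses a variance-of-allele-size moment estimate. The
"recent" horizon often quoted for these tests (some hundreds of
generations) is a reporting annotation: the statistics themselves carry no
time units. Power depends strongly on the crash geometry and the number of
loci; the test suite demonstrates both the calibrated size under constant
size and a clear signal shift under a 40-fold recent crash across twelve
loci.

## The twelve mutation models

Each model is a continuous-time Markov chain on the repeat lattice defined
by three switches: total mutation rate per allele either **E**qual
(`alpha`) or **P**roportional to length (`alpha (i - i_min + 1)`);
directional bias **U**nbiased, **C**onstant, or **L**inear in length, with
the expansion probability a logistic function
`gamma_i = plogis(b0 + b1 (i - i_min))` (logistic rather than linear
regression keeps probabilities in `(0,1)` on any lattice); and step law
**1** (single step) or **2** (geometric multi-step — "two-phase" in the
sense of one-or-more repeats, not literally at most two). The LINEAR
covariate is the lattice position `i - i_min`, which makes the bias
shift-invariant and numerically tame.

Boundary handling is direction-truncation: the geometric step mass in a
direction is renormalized over the steps that fit, and at a boundary state
the blocked direction's mass is dropped entirely, so boundary states mutate
at a reduced total rate. Every generator is rescaled so the
stationary-weighted mean mutation rate is exactly one, which makes branch
lengths (expected mutations) comparable across models. Matrix exponentials
use an eigen-decomposition cache (complex-safe for the non-reversible
biased multi-step chains) with a dense scaling-and-squaring fallback; the
test suite checks `exp(Qt)` against an independent dense exponential and
the one-step chains against their detailed-balance closed forms (uniform
for EU1; `pi_i` proportional to `1/(i - i_min + 1)` for PU1).

Default bias and step parameters (`b0 = 0.5` for C, `b0 = 2, b1 = -0.2`
for L, mean step 2.8 for multi-step models) are fixed, declared model
constants rather than estimated quantities: the model-comparison machinery
ranks these twelve concrete chains.

## Coalescent simulator

Genealogies follow the time-inhomogeneous Kingman coalescent with pairwise
rate `1/theta(t)`; waiting times use exact time-rescaling inversion
(closed-form for constant and exponential trajectories, segment-walk for
piecewise-constant ones). Time is measured in expected mutations per
lineage, so `theta` is the mutation-scaled population size with
`E[T2] = theta`; conversion to natural units happens only at the reporting
stage via `years = (height/mu) * generation_time` and `Ne = theta/(4 mu)`.

The synthetic-data generator emulates the study conditions the package was
built around: 85 diploid individuals in six social groups (32/32/5/5/5/6)
connected by high gene flow (`4Nm = 100` by default, the middle of the
high-migration regime), ten loci on `[1, 35]`, and a per-call missing rate
of 0.028 matching the observed genotyping completeness. The default
mutation model and size (single-step, `theta = 4`) were chosen once because
they reproduce the emulated study's per-locus allele-count spread (3-14)
and heterozygosities near 0.7; they are not adjusted per analysis. With
several groups the generator runs an n-island structured coalescent
(constant size only) and pairs gene copies into diploids uniformly within
demes — random mating, consistent with the panmixia such data support.

What the generator does *not* emulate: genotyping error and allelic
dropout, ascertainment of polymorphic loci, linked loci, selection, and
spatial geometry beyond the symmetric island model. Passing tests on
synthetic data therefore validate the estimators under the stated
generative model, not robustness to those artefacts.

## Skyline inference

The demographic model is either a constant size `theta` with a bounded
Jeffreys (one-on-x) prior, or a piecewise-constant trajectory whose number
of change points `psi` has a Poisson prior with mean `lambda = log 2` —
chosen so that "no change at all" carries prior probability one half —
with change times uniform on a bounded window and segment sizes exponential
around a mean `phi` that itself has a bounded one-on-x prior. One-on-x
priors are given explicit bounds (defaults `1e-4` to `1e3`) to be proper.
Per-locus genealogies over the `2N` exchangeable gene copies are latent
variables; the two gene copies of an individual are independent tips, the
standard treatment for unlinked autosomal loci. Per-locus mutation-rate
modifiers are fixed from observed allele counts scaled to mean one — a
declared convention for the rate-variation adjustment, since allele count
is the simplest observable proxy for locus mutability.

The sampler is Metropolis-within-Gibbs: node-height slides, root-gap
multipliers, narrow subtree exchanges, whole-tree scalings, and an
independence redraw of a whole genealogy from its coalescent prior
(accepted on the likelihood ratio alone — very effective for small trees
and exact for prior sampling); segment-size multipliers; change-time
slides; reversible-jump birth/death moves for `psi` that propose from the
prior, so their acceptance ratio collapses to the Poisson ratio times the
coalescent ratio; and a joint up-down move rescaling sizes, change times
and genealogy heights together, which is what lets mutation-scaled size and
tree height mix despite their strong posterior correlation. Under the
constant model, `theta` is additionally drawn exactly from its truncated
inverse-gamma full conditional. Tip likelihoods use Felsenstein pruning
with per-node rescaling; missing tips carry all-ones partials.

Chain-correctness is tested rather than assumed: sampling with the
likelihood forced to one reproduces the Poisson prior on `psi`
(chi-squared goodness of fit) and the truncated one-on-x marginal on
`theta` (Kolmogorov-Smirnov); a two-tip single-locus posterior matches 2-D
quadrature on the posterior mean within 2%; and constant-size synthetic
data yield `psi` mode zero with calibrated 95% HPD coverage of the true
`theta` across replicates. The change-point scheme (free change times with
reversible jump, rather than change points tied to coalescent events) is a
deliberate divergence from the scheme inside the well-known skyline
samplers: it is simpler to implement, to test against the prior, and to
reason about, at the cost of some statistical efficiency for very sharp
histories.

Defaults: burn-in 10%, thinning targeted at no more than 2,000 retained
samples, seeds mandatory for reproducibility. `T_COAL`, the height of the
tallest genealogy at each retained step, summarizes how deep in time the
data carry signal; skyline curves beyond it are prior-driven. HPD intervals
use the shortest-contiguous-interval estimator on sorted samples.

## Model comparison

Log marginal likelihoods come from the harmonic mean of sampled
log-likelihoods (computed in log space with max-shift stabilization, Monte
Carlo error by block bootstrap) — the estimator used by the classic trace
analyzers — or, preferably, from stepping-stone integration over a grid of
power posteriors (`beta = (k/K)^(1/0.3)`), which the test suite shows has
visibly lower spread on a conjugate toy. Models are ranked by
`ln BF = ln mL_best - ln mL_i` with the conventional "decisive" label above
5, and relative model probabilities are a max-shifted softmax of the
`ln mL` values.

## Numerical choices and problem sizes

Tolerances: generators are validated to row sums `1e-10`; pruning against
exhaustive enumeration to `1e-9`; piecewise coalescent densities against
quadrature to `1e-8`. Degenerate inputs have defined behaviour:
monomorphic loci are skipped (with warnings) where a statistic is
undefined, `M = 1` is reported with a flag, and all-missing tips contribute
likelihood one. Tie-breaks (NJ deepest split, mode-shift bins) are
deterministic.

The test suite and the acceptance script run everything at deliberately
small problem sizes — tens of individuals, a handful of loci, chains of a
few thousand sweeps, twenty replicates for coverage checks — chosen as the
smallest sizes at which the distributional checks retain discriminating
power. The full study-scale preset (85 individuals, ten loci) is exercised
for the summary-statistic, structure and bottleneck stages; skyline chains
at that scale are demonstration-length in the pipeline defaults and should
be lengthened (and preferably switched to stepping-stone marginal
likelihoods) for production analyses.

## Known limitations

- Because change times are free parameters on a bounded window, change
  points proposed beyond the tallest sampled genealogy are
  likelihood-neutral and are restrained only by the Poisson prior; the
  `psi` posterior is therefore mildly inflated relative to samplers that
  tie change points to coalescent events. A flat inferred trajectory with
  `psi = 0` inside the credible set remains the stability signature.
- The harmonic-mean marginal likelihood is biased-high with heavy-tailed
  weights; it is retained for comparability with the classic workflow, with
  stepping stone provided as the better alternative.
- Mutation-model bias/step parameters are fixed model constants, not
  sampled; model comparison is over the twelve concrete chains.
- The structured simulator covers constant-size island models only; it is
  a screening tool, not a migration-inference engine.
- Microsatellite ascertainment (loci chosen because they are polymorphic)
  is ignored, as it is in the analyses this package mirrors.
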