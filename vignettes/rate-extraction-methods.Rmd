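---
title: "Relaxed-clock rate extraction around ancient gene duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxed-clock rate extraction around ancient gene duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(paraclock)
```

## The problem

Several core components of the photosynthetic and bioenergetic machinery —
the D1/D2 and CP43/CP47 pairs of photosystem II, the Alpha/Beta subunits of
F-type ATP synthase — arose by gene duplications that predate the most
recent common ancestor (MRCA) of Cyanobacteria, possibly by a very long
time. Because the sequence divergence between such paralogs is essentially
fixed, any assumption about the *time span* between the duplication and the
crown ancestor (called ΔT here) translates directly into a requirement on
the *rate* of protein evolution near the duplication. `paraclock`
implements this bookkeeping quantitatively:

* a Bayesian relaxed molecular clock on a fixed rooted topology extracts
  per-branch rates (amino-acid substitutions per site per Ga, written
  δ Ga⁻¹) under explicit age calibrations;
* ν_max is the mean posterior rate on the two branches incident to the
  duplication node, ν_min the mean posterior rate over branches whose
  midpoint age falls in the Proterozoic window; their ratio summarises how
  much faster evolution must have been at the duplication;
* sweeping the crown-MRCA calibration over a grid of ages traces
  ν_max/ν_min as a function of ΔT, which follows a power law when the
  total divergence is held fixed;
* an exponential decay `r(t) = plateau + (r0 − plateau)·exp(−λ(t_root − t))`
  fitted to the rate-through-time profile summarises the Archean
  deceleration with a stabilisation in the Proterozoic.

A marginal ancestral-sequence-reconstruction module reconstructs the
pre-duplication ancestor (the "D0"-style node) with per-site posterior
probabilities and explicit indel handling, and a corrected-distance module
provides the classical within-group divergence summaries with bootstrap
errors.

## The model

**Likelihood.** Felsenstein pruning over the 20 amino-acid states under an
empirical exchangeability matrix (Poisson, JTT, WAG or LG) with equilibrium
frequencies (matrix-supplied, uniform, empirical, or user-given) and
discrete-gamma rate heterogeneity (mean-category discretisation, 4
categories by default). The rate matrix is normalised to one expected
substitution per site per unit branch length, so branch lengths are always
expected substitutions/site. Gap characters are missing data: a gapped tip
contributes a unit partial vector, and an all-gap column contributes
exactly zero log-likelihood. The kernel is compiled (RcppArmadillo) and
caches per-edge messages, so a Metropolis proposal that changes a few
branches only recomputes the path to the root.

The package deliberately uses fixed empirical matrices rather than
site-profile mixture models: profile mixtures are cluster-scale machinery
whose stochastic site clustering is orthogonal to the ΔT framework studied
here, and every inference the package reports is validated against its own
forward simulator under the same fixed-matrix family.

**Chronogram parameterisation.** Node ages are absolute (Ga before
present), tips at age 0. Branch length = rate × duration. Under the
autocorrelated-lognormal rate model, log-rates live on *nodes* and evolve
as Brownian motion with variance `sigma2` per Ga; a branch's rate is
`exp` of the mean of its two endpoint log-rates. The forward simulator
uses the identical discretisation, so simulation and inference are
conjugate and parameter-recovery tests are meaningful. No drift correction
is applied to the Brownian walk (geometric-median parameterisation). The
alternative rate model is uncorrelated: i.i.d. gamma rates per branch.

**Calibrations.** An age constraint applies to the MRCA of a named set of
leaves, or to the root (a root calibration is required, since the
uniform-on-ages prior is conditioned on a proper root age). Hard bounds
are uniform with impossible tails. Soft bounds place a uniform core
holding 95% of the mass inside the interval and exponential tails,
density-continuous at each bound, holding exactly 2.5% per side (5% for
the single tail of a one-sided bound). The exponential tail family is the
package's choice — only the tail masses, not the family, are fixed by
convention — and the tail masses are verified by quadrature in the test
suite. One-sided calibrations close their unbounded side with a wide
uniform core ending at `core_cap` (default 4.6 Ga, the age of the Earth)
so that every calibration is a proper density.

**Age prior.** Default is uniform-on-ages: given the root age, non-root
internal ages are jointly uniform over the topology-compatible region,
contributing `1/root^(n−1)`; the root age then follows its calibration
density exactly, which the prior-only sampling test checks by a
Kolmogorov–Smirnov comparison. A birth-death prior (kernel density with
birth rate λ, death rate μ, sampling fraction ρ, conditional on the root
age) is available; its kernel is verified to integrate to 1 by quadrature.

**Hyperpriors.** `sigma2 ~ Gamma(2, rate 0.5)` (mean 4): the Archean decay
scenarios studied here require log-rate swings of ~3 over fractions of a
Ga, which a tight sigma2 prior would suppress into over-smoothed rates;
this default admits them while keeping finite mass near zero. The root
log-rate is Normal(0, 2) on the log scale (median 1 δ Ga⁻¹, 95% interval
~0.02–50). The discrete-gamma shape, when sampled, has a Gamma(2, 1)
prior.

## The sampler

Metropolis-within-Gibbs, one sweep =

1. one age update per internal node — uniform independence proposal inside
   the (max child age, parent age) interval, which is symmetric because
   the interval depends only on the neighbours; the root slides in a
   window (default 0.4 Ga);
2. one Gaussian random-walk update per node log-rate (default sd 0.4);
3. one *global* log-rate shift and one *subtree* log-rate shift (all
   log-rates below a random node move together) — these traverse the
   decaying-rate profile orders of magnitude faster than single-node
   walks, at the cost of one full or partial likelihood recomputation;
4. a sigma2 log-multiplier move (prior-only);
5. optionally a gamma-shape log-multiplier move (full likelihood
   recomputation, attempted every `alpha_every` sweeps);
6. a whole-tree age-scaling multiplier move with Jacobian `c^(n internal)`.

All randomness flows from named seeds (per-chain seeds derived
deterministically from the master seed), so identical settings give
bit-identical chains. Chains are initialised from calibration-consistent
random ages; when the likelihood is active, the log-rates start at
maximum-likelihood branch lengths (estimated on the fixed topology)
divided by the initial durations — a standard warm start that shortens
burn-in dramatically and whose asymmetry across the two root branches is
immediately regularised by the Brownian prior. Convergence is advisory:
split-Rhat and a Geyer-style effective sample size are reported for every
scalar, with a warning (never an error) above Rhat 1.1, so that short
scripted runs remain usable.

Retained draws are summarised per branch into a rate-through-time profile:
posterior-mean midpoint age, posterior-mean rate, and Monte-Carlo standard
errors (posterior SD divided by the square root of the effective sample
size, which is the error bar convention used throughout).

## ΔT scenarios

`scenario_sweep()` re-fits the clock once per crown-MRCA age on a grid,
replacing that calibration with a narrow hard interval (half-width 0.05 Ga
by default) while holding everything else fixed, and reports each
scenario's ν_max ± SE, ν_min ± SE, float ratio and *reported* ratio. The
reported ratio is the float ratio truncated toward zero — the only integer
convention consistent with the worked examples the package reproduces
(7.32/0.28 → 26, 6.02/0.28 → 21, 10.22/0.25 → 40). One worked scenario
pairs a duplication at 3.5 Ga with a crown MRCA at 1.7 Ga, i.e. ΔT =
1.8 Ga; note that for the companion 2.6 Ga scenario some sources print
ΔT = 1.1 Ga where the subtraction gives 0.9 Ga — `compute_delta_t()`
always returns the arithmetic value and this discrepancy is deliberately
not reconciled.

Two operational choices in `nu_extrema()` are exposed as parameters
because the quantities are not fully pinned down by convention: ν_max
defaults to the *mean* over the two duplication-incident branches (option:
the single fastest), and the ν_min window defaults to branches with
posterior-mean midpoint age below 2.5 Ga, the Archean–Proterozoic
boundary.

## The synthetic-data generator

`simulate_timetree()` draws a coalescent-shape ultrametric topology
rescaled to a chosen root age. `make_duplication_dataset()` mirrors the
species chronogram into two paralog subtrees (`_A`/`_B` suffixes) joined
at a duplication node, simulates branch rates, simulates an alignment
(root sequence from equilibrium, per-site gamma categories, matrix
exponentials down the tree; no indels), and stores a truth record (ΔT,
realised ν_max, ν_min, ratio) that is recomputable from the stored tree.
Rates come either from the autocorrelated process started at a fast root
rate, or from a deterministic exponential envelope evaluated at branch
midpoints. For recovery experiments with a *stated* truth ratio R, the
envelope amplitude is solved in closed form (the ratio is
linear-fractional in the amplitude), with decay constant λ = 2 Ga⁻¹ and
plateau 0.25 δ Ga⁻¹ by default — plateau and window chosen to sit in the
0.1–0.3 δ Ga⁻¹ range typical of slowly evolving bioenergetic proteins,
and λ fast enough that rates have stabilised well before the Proterozoic
window.

What the generator deliberately does not emulate: indel processes (ASR
indel operations are exercised on hand-built gapped fixtures),
site-profile heterogeneity beyond discrete-gamma, alignment error, and
non-extant sampling. Passing recovery tests therefore demonstrate
correctness of the inferential machinery under the stated generative
model, not robustness to real-data model violations.

## Ancestral reconstruction

`marginal_asr()` computes, for one target node, the per-site posterior
over the 20 residues by inside–outside passes of the pruning recursion,
integrating over the discrete-gamma categories; only marginal (not joint)
reconstruction is provided, because per-site posterior probabilities are a
marginal quantity. MAP ties are broken alphabetically for determinism.
Whether the target carries a residue at all is a separate 2-state problem:
either a symmetric-rate Markov chain on gap presence/absence (residue
emitted iff PP(present) ≥ 0.7 by default) or Fitch parsimony with
ambiguities at the target resolved to "present". The indel chain reuses
the input branch lengths scaled by a user multiplier (default 1), since no
indel-specific rate calibration is attempted. Multi-model consensus is
emulated by running `marginal_asr()` under several substitution models and
comparing MAP sequences with `compare_reconstructions()` (identity on
mutually unmasked sites, mean ± SD over pairs, simple unweighted means for
the per-site PP summaries).

## Distances

Identity and p-distance use pairwise deletion (a column is compared only
if neither member is gapped); this is the convention that keeps toy
fixtures exact and matches the default behaviour of the standard
distance tools in the field. Corrections: Poisson `d = −ln(1−p)` and
gamma-Poisson `d = α((1−p)^(−1/α) − 1)` (α = 1 by default, matching the
classical settings). The matrix-based distance is a one-dimensional
maximum-likelihood distance under the chosen matrix + Γ, maximised by
bounded search on [0, 20] substitutions/site; under the Poisson matrix
with one category it inverts the 20-state closed form
`p = (19/20)(1 − e^{−20d/19})`, which the tests check to 1e-4.
Within-group means average all unordered pairs, with the SE taken as the
SD of that mean over 500 site-bootstrap replicates (columns resampled with
replacement, one seed per result). Pairs observed at p = 1 are dropped
from correction-based means as saturated rather than mapped to infinity.
In the identity-based deduplication (`dedup_by_identity()`, threshold
0.92), identity excludes only gap–gap columns, records are visited longest
first, and inputs must be pre-aligned or of identical length — a
documented limitation, since word-based heuristics of dedicated clustering
tools are out of scope.

## Numerical choices and degenerate inputs

* Eigendecomposition of the reversible rate matrix via the symmetric
  similarity transform, so eigenvalues are real by construction; tiny
  negative entries of `P(t)` are clamped to zero and rows renormalised.
* Per-site, per-node rescaling of partial likelihoods (joint across
  categories) guards against underflow on deep trees.
* Site columns that are entirely gaps are retained and contribute zero
  log-likelihood rather than being silently dropped.
* `filter_columns()` keeps a column iff its gap fraction ≤ 0.5 by
  default; the occupancy filter replaces block-based trimming because the
  paralog analyses only need indel-dominated columns removed, and all
  user-facing column reports are 1-based (R convention).
* `fit_exponential_decay()` runs five deterministic starts through
  Levenberg–Marquardt with non-negativity bounds and keeps the best RMSE;
  exactly constant input returns the zero-amplitude curve directly.
* Ratio reporting truncates toward zero; the float ratio is always
  reported alongside.
* The identity of a pair with no mutually ungapped column is an error
  (undefined), never silently 0 or 1.

## Problem sizes used in the validation suite

The test suite and the acceptance script validate the pipeline end-to-end
on synthetic duplication datasets of 16 species × 2 paralogs and 500
columns (the scale at which the scientific claims are property-tested),
with reduced sampler lengths (hundreds of sweeps after a
maximum-likelihood warm start, 1–2 chains) — sizes chosen so the entire
suite runs on a single CPU in minutes while leaving the recovery
tolerances comfortably met. Production analyses should use the defaults
(4 chains × 20 000 sweeps, 25% burn-in, thinning 10) and treat the
reported split-Rhat values as the stopping criterion.

## Known limitations

* Fixed topology: no tree search, and no accounting for topological
  uncertainty.
* Fixed empirical matrices: no site-profile mixtures (CAT-style models);
  rates extracted under profile mixtures can differ systematically.
* The uniform-on-ages prior, while proper given the root calibration, is
  informative about non-root node ages in ways birth-death priors are
  not; both are provided, neither is "assumption-free".
* ν_max depends on the operational definition at the duplication node
  (mean vs fastest incident branch); both are reported options.
* The ML warm start biases nothing asymptotically but means very short
  chains are not prior-correct; prior-only runs never use it.
* Bootstrap SEs for ML-matrix distances at large group sizes are
  computationally heavy (one bounded optimisation per pair per
  replicate).
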