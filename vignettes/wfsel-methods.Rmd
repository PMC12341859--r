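---
title: "Inferring diploid selection from temporal allele counts: model and methods"
author: "wfsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring diploid selection from temporal allele counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfsel)
```

## The problem

Time-stratified genetic samples — ancient-DNA series spanning millennia, or
evolve-and-resequence (E&R) experiments sampled every few generations — let
us watch allele frequencies move.  `wfsel` asks, locus by locus, whether the
observed movement is explained by genetic drift alone or requires natural
selection, and if so how strong and how dominant that selection is, and
when it began.

## The model

### Wright–Fisher dynamics with general diploid selection

A biallelic locus segregates alleles $a$ and $A$ (the focal allele,
typically the derived or ALT allele) in a panmictic diploid population of
constant effective size $N_e$.  Genotypes $aa$, $aA$, $AA$ have relative
fitnesses $1$, $1 + s_{Aa}$, $1 + s_{AA}$.  Both coefficients are free
("general diploid selection"); the familiar one-parameter families arise
through a dominance coefficient $h$ via $s_{Aa} = h\,s$, $s_{AA} = s$
(`fitness_from_sh()`): $h = 0.5$ is additive, $h = 1$ dominant, $h = 0$
recessive.  Selection coefficients may change over time in a piece-wise
constant way (`sel_schedule()`); a two-epoch schedule with a neutral first
epoch models an onset of selection at generation $t_0$
(`onset_schedule()`).

One generation maps the frequency $x$ of $A$ deterministically through
viability selection,
$$x^\ast = \frac{x^2 (1+s_{AA}) + x(1-x)(1+s_{Aa})}
{x^2 (1+s_{AA}) + 2x(1-x)(1+s_{Aa}) + (1-x)^2},$$
then recurrent mutation, $x' = x^\ast(1-u_{10}) + (1-x^\ast)u_{01}$
(selection before mutation; the order is a documented convention — the
difference is $O(u\,s)$ per generation, far below every other
approximation error here).  Reproduction then draws the next generation
binomially: $x_{t+1} = B/2N_e$ with $B \sim \mathrm{Binom}(2N_e, f(x_t))$,
where $f$ is the composed deterministic map.  Time is measured in integer
generations, forward from the analysis start; calendar-year conversion is
the caller's responsibility.

### The hidden Markov model

The data at a locus are time-stamped binomial samples: at generation
$t_k$, $c_k$ of $n_k$ sampled haploids carry $A$ (a diploid individual
contributes two observations, a pseudo-haploid aDNA genotype one, missing
data zero).  The population frequency is the hidden state:

* **Transitions.** The frequency interval $[0,1]$ is discretized
  (`freq_grid()`: dedicated boundary states at exactly 0 and 1, uniform
  interior points, midpoint integration cells).  The transition over an
  inter-sample interval is built from Gaussian approximations of the
  per-generation dynamics: sub-step kernels whose mean is the composed
  deterministic map and whose variance follows
  $$v_{g+1} = v_g\,f'(m_g)^2\,(1 - \tfrac{1}{2N_e})
  + \frac{m_{g+1}(1-m_{g+1})}{2N_e},$$
  integrated exactly over the grid cells, with Gaussian tail mass below 0
  (above 1) collected into the boundary state so that drift-driven
  absorption is retained.  In the neutral mutation-free case this variance
  recursion reproduces the exact Wright–Fisher variance
  $x(1-x)\bigl(1-(1-\tfrac{1}{2N_e})^{t}\bigr)$.
* **Emissions.** $\Pr(c_k \mid x) = \mathrm{Binom}(c_k; n_k, x)$, with
  sample size 0 emitting probability 1.
* **Initial condition** at the first sampling time
  (`init_fixed()`, `init_uniform()`, `init_beta()` — the stationary
  $\mathrm{Beta}(4N_e u_{01},\, 4N_e u_{10})$ density — or
  `init_explicit()`).

The forward algorithm with per-step scaling returns the log-likelihood
(`forward_loglik()`); `batch_loglik()` vectorizes it across loci that share
sampling times, computing each transition matrix once — this sharing is
what makes genome-scale scans cheap.  Intervals spanning epoch boundaries
are composed from per-epoch matrices, which is exact at the discretized
level for piece-wise constant selection.

## Numerical choices

These are the package's own numerical decisions; each is pinned by a test.

* **Time slicing of transitions.** A single Gaussian over a long interval
  is a poor approximation when the elapsed time is an appreciable fraction
  of $N_e$ generations (the true transition density is then visibly
  non-Gaussian, with boundary spikes).  Intervals are therefore sliced
  into sub-steps of at most $\max(1, \mathrm{round}(0.0025\,N_e))$
  generations and the sub-step kernels multiplied (binary
  exponentiation).  This keeps each kernel short relative to $N_e$ *and*
  its standard deviation resolved by the default grid at all interior
  frequencies, for any $N_e$.  Validated against the exact discrete chain
  (below).
* **Grid.** 500 uniform interior points plus the two boundary states by
  default.  When the population lattice is coarser than the grid
  ($2N_e + 1 \le$ grid size), `default_grid()` aligns the grid to the
  population allele counts $i/2N_e$; the midpoint cells then coincide with
  the continuity-corrected integration ranges of the count states, which
  removes aliasing between the smooth kernels and the lattice chain.
  A geometric boundary-refinement option exists (`freq_grid(refine =)`),
  but on these problems plain uniform grids with lattice alignment at
  small $N_e$ performed best.
* **Degenerate variance** (e.g. `dt = 0`, or an absorbing boundary without
  mutation): the transition row is a point mass on the cell containing the
  mean — the limit of the Gaussian.
* **Exact small-population reference.** `wf_exact_loglik()` implements the
  HMM over the exact $2N_e+1$-state binomial Wright–Fisher chain, with no
  Gaussian approximation and no frequency discretization.  It is the
  independent oracle for the approximation: at $N_e = 100$, five samples
  of 40 haploids over 200 generations, neutral and $|s| = 0.02$ scenarios
  (additive, dominant, negative), the absolute log-likelihood gap stays
  below 0.1 across random count configurations.
* **Non-integer times are rejected**; the per-generation recursion defines
  the model.

## Inference

`scan_s()` evaluates the per-locus log-likelihood on a linear or geometric
grid of $s = s_{AA}$ values at fixed $h$ (`make_grid()`); `scan_2d()`
scans the full $(s_{Aa}, s_{AA})$ plane (on-grid maxima only — off-grid
interpolation is deliberately restricted to 1D sections).  From a 1D
surface, `interpolate_mle()` reports

* the **on-grid MLE** (ties broken toward the smaller $|s|$, then the
  negative value — conservative toward neutrality and deterministic);
* the **off-grid MLE**, the maximizer of a cubic-spline interpolant
  (Forsythe–Malcolm–Moler end conditions, which reproduce polynomial
  surfaces exactly — an exact quadratic's maximizer is recovered to
  $10^{-9}$), clamped to the grid range, falling back to the on-grid node
  at boundary maxima or with fewer than three grid points;
* the **likelihood-ratio statistic**
  $\Lambda = \max(0,\, 2(\ell_{\max} - \ell_0))$ against neutrality and
  its p-value from $\chi^2_1$ — appropriate for the single free parameter
  of a fixed-$h$ scan.  The floor absorbs tiny negative values that spline
  interpolation can produce.

`estimate_onset()` evaluates two-epoch schedules on an onset grid crossed
with an $s$ grid and reports the onset coordinate of the joint argmax (a
marginal point estimate; no profile smoothing).  `fisher_combine()` merges
per-replicate p-values (E&R biological replicates) via
$-2\sum_k \ln p_k \sim \chi^2_{2k}$.

## The simulator

`simulate_samples()` draws replicate trajectories by *discrete binomial*
Wright–Fisher reproduction — deliberately not the Gaussian approximation,
so that simulation and inference are independent model realizations and
recovery tests are meaningful.  Counts are drawn binomially from the
trajectory at the sampling times.  Replicate filters (segregating pooled
sample, pooled minor-allele frequency, final population frequency in
$(0,1)$) are applied by rejection: the output is explicitly the
conditional distribution given the filter, and the attempt count is
recorded.  One RNG stream is seeded once and the batch-drawing scheme is
fixed, so a given `(seed, n_rep, filters)` reproduces bit-identical
output.

## Study design used by the statistical checks

The acceptance checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use a temporal design of nine samples 500
generations apart with 20 diploids (40 haploids) per time and
$N_e = 10^4$; the onset experiment samples 50 diploids per time, with
selection switched on at generation 2000.  Unspecified aspects were fixed
once as follows and not revisited:

* **Initial frequency**: drawn uniform on $(0,1)$ — standing variation.
  (A low fixed starting frequency such as 0.01 was considered and
  rejected: at $N_e = 10^4$ the allele is then usually lost during the
  neutral epoch, leaving most replicates with no information, which
  contradicts the onset-recovery and power behaviour this design is meant
  to exhibit.)
* **Replicate conditioning**: pooled sample segregating (the analogue of
  ascertaining a polymorphic site).
* **Inference settings**: matching uniform initial distribution, linear
  $s$ grid of 41 points on $[-0.02, 0.02]$ at $h = 0.5$; onset grid
  $\{0, 500, \ldots, 4000\}$ with $s \in \{0.002, 0.005, 0.01, 0.02,
  0.05\}$.

Under this design the suite verifies: $\chi^2_1$ calibration of neutral
p-values (fraction below 0.05 within $[0.02, 0.09]$ over 1000 replicates);
median off-grid MLE within 50% of a true $s_{AA} = 0.005$ over 200
replicates; median onset estimate within $\pm 500$ generations of 2000
over 100 replicates; and power above 50% at $s_{AA} = 0.005$ against the
empirical neutral 95th percentile.  Problem sizes are the package's
choices for routine re-verification; all scale up linearly.

## What the simulations do and do not show

The generator emulates a single panmictic population of constant size with
independent biallelic loci, exact sampling times, and binomial sampling of
alleles.  Real data violate parts of this: population structure and
migration, size changes, linkage between loci, uncertain dating,
reference/damage biases in aDNA genotypes, and pool-seq noise in E&R data
are all absent.  Passing tests therefore demonstrate correctness of the
method under its own model, not robustness to these violations.  In
applications the effective population size must be supplied and
misspecification propagates directly into the selection estimates; the
model also assumes constant $N_e$ and constant mutation rates throughout.

## Known limitations

* 2D surfaces report on-grid maxima only; no confidence intervals or
  posteriors are provided (users may apply their own profile or Bayesian
  machinery on the exported surfaces).
* No multiple-testing correction is applied; genome scans should correct
  p-values by their preferred procedure.
* The VCF reader takes ALT as the focal allele and does not polarize by
  ancestral state; genotype likelihoods (PL/GL) are not used.
* `-Inf` log-likelihoods are possible for data that are strictly
  impossible under a point-mass initial condition without mutation.
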