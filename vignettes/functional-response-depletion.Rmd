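---
title: "Fitting depleted-prey functional responses: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting depleted-prey functional responses: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements: the models, their assumptions, the numerical choices, and the
places where the design was genuinely open and a choice had to be made.

## The depletion model

A type II functional response describes a forager whose kill rate
saturates with prey density because each capture costs a fixed handling
time $T_h$ during which no searching happens. In a closed arena where
killed prey are not replaced, the prey density also falls over the
exposure, so the classical Holling disc equation
$N_e = a N_0 T / (1 + a T_h N_0)$ (implemented as `holling_expected()`)
overestimates consumption. The expectation that accounts for depletion is
the Rogers random-predator equation,

$$N_e \;=\; N_0\left[1 - \exp(a T_h N_e - aT)\right],$$

an implicit equation in $N_e$. `rogers_expected()` solves it through the
Lambert-W closed form

$$N_e \;=\; N_0 - \frac{W_0\!\left(a T_h N_0\, e^{\,a T_h N_0 - aT}\right)}{a T_h}.$$

Assumptions worth keeping in view: a single forager (or a fixed number
whose joint behaviour is absorbed into $a$), random search, constant $a$
and $T_h$ over the exposure, and no prey escape or natural mortality (the
assay design this package mirrors verified control survival above 98.5%,
so background mortality is ignored).

### Why one time unit = one exposure period

The three parameters share one time unit and the package default is
`duration = 1`, i.e. rates per 24-h assay period rather than per hour.
This is deliberate. The bundled reference estimates
(`fr_reference_params()`, e.g. $a = 1.590$, $T_h = 0.006$ for a single
ladybird with aggregated prey) produce sensible saturating curves only on
that scale: read as per-hour rates with $T = 24$ h, $aT \approx 38$ would
drive $1 - e^{-aT}$ to 1 and predict total consumption of all 256 aphids
at every density, which no ladybird achieves and no reported curve shows.
On the per-period scale the same numbers give a saturation ceiling of
$T/T_h \approx 167$ prey and an expected kill of about 109 at
$N_0 = 256$ — the shape the published curves display. A handling time of
0.006 periods is about 9 minutes per aphid, biologically plausible for a
coccinellid. `duration` remains an explicit argument throughout, so data
recorded on other time scales can be analysed without rescaling by hand.

## Numerical choices

**Lambert W.** The W argument $a T_h N_0 e^{a T_h N_0 - aT}$ is
non-negative for admissible parameters, so only the principal branch
$W_0$ is ever needed; the internal solver asserts non-negativity. It is a
vectorised Halley iteration started at $\log(1+x)$ (8–10 iterations to
machine precision), and when $a T_h N_0$ is large enough that the argument
overflows double precision, a log-domain Newton solver for
$w + \log w = y$ takes over. `rogers_expected_bisect()` implements the
same root by bracketed bisection on $[0, N_0]$ — the residual is positive
at 0 and negative at $N_0$ — and the two routes are required to agree to
$10^{-8}$ across a parameter grid in the test suite, alongside an
independent Brent-method oracle.

**Degenerate parameters.** $a = 0$ returns 0 and $T_h = 0$ returns the
explicit random-search limit $N_0(1 - e^{-aT})$; neither divides by zero.

**Likelihood and optimizer.** The observation model is
$\text{killed}_i \sim \text{Binomial}(N_{0,i},\, N_e(N_{0,i})/N_{0,i})$.
Kill probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ so boundary
parameter values keep the objective finite. Optimization runs on
$(\log a, \log T_h)$ — positivity built in, and the two parameters' very
different magnitudes (a handling time of $6\times10^{-3}$ next to an
attack rate near 2) are tamed — using L-BFGS-B with an analytic gradient
obtained by implicit differentiation of the Rogers root:
$\partial N_e/\partial a = N_0 E (T - T_h N_e) / (1 + a T_h N_0 E)$ and
$\partial N_e/\partial T_h = -N_0 E\, a N_e / (1 + a T_h N_0 E)$ with
$E = 1 - N_e/N_0$. Starting values come from a coarse $5\times5$ grid
around moment heuristics (attack rate from inverting the random-search
limit at the lowest density; handling time from the saturation ceiling),
plus 10 jittered restarts (log-uniform $\pm 1$, seed-controlled). Standard
errors use the inverse of the numerically differentiated Hessian at the
optimum, delta-mapped back to the natural scale; Wald $z$ and two-sided
$p$ are reported per parameter. Within-test verification: the optimum is
checked against a $200\times200$ grid search, and the log-scale fit
against a box-constrained natural-scale fit.

**Bootstrap.** The resampling unit is the whole trial (cage): cages are
independent by design, and a residual bootstrap is unattractive for a
discrete response. Each of the (default) 2000 resamples is refitted
starting from the original estimates, failures are dropped and counted
(never imputed — silent imputation would bias the intervals), and the
result is flagged unstable beyond 20% failures. Intervals are percentile
intervals, the convention of the functional-response literature this
package follows; BCa was considered and rejected to keep the draws
directly reusable for curve bands. Bands are pointwise 2.5%/97.5%
quantiles of the prediction curve across draws.

**Band comparison.** Two treatments are compared by pointwise interval
disjointness on a shared density grid with step 1 prey — consistent with
reported integer thresholds for where responses differ — and consecutive
disjoint densities are merged into closed intervals. No multiplicity
correction is applied, matching field practice; the report is descriptive
(where do the 95% bands separate), not a family-wise test.

**Type screen.** The logistic regression is an ordinary binomial GLM
(IRLS, deviance tolerance $10^{-10}$); the test suite re-derives the
coefficients with a hand-rolled IRLS oracle. The polynomial degree is
exposed (`degree` in 1–3, default 2): the classical screen uses a cubic,
but published tables in this literature report only the linear term, so
the degree actually used elsewhere cannot be assumed — degree 2 keeps the
rising-then-falling signature detectable without the cubic's conditioning
problems at densities up to 256. Wald $p$-values are used for
classification, matching how linear coefficients are reported in such
tables. Non-convergence and separation are reported as `inconclusive`
rather than raised, since the correct downstream action (do not fit) is
the same.

**Observation-level GLMM.** With one latent intercept per cage the
marginal likelihood factorizes into independent one-dimensional
integrals; each is computed by adaptive Gauss–Hermite quadrature (default
15 nodes) centred at the observation's conditional mode, found by Newton
on a log-concave objective. Nodes and weights come from the Golub–Welsch
eigendecomposition. `(β, log σ)` is maximized by BFGS from the GLM
solution. This design makes the likelihood directly testable: the suite
checks it against brute-force trapezoid integration ($10^{-6}$ per
observation), against `lme4::glmer` with `nAGQ = 25` ($10^{-3}$ on
coefficients), and for stability between 11 and 31 nodes ($10^{-4}$).
When the variance component collapses ($\hat\sigma < 10^{-2}$ or no
likelihood gain over the GLM), the model is refitted as a plain GLM with
`olre_sd = 0` and a boundary flag — at $\sigma = 0$ the mixed model *is*
the GLM. Density enters untransformed (prey counts) by default with a
`center` option; the distribution treatment is a 0/1 indicator with
`aggregate` as reference. Wald statistics are labelled $z$: they are
normal-theory ratios, and no residual-df $t$ reference is defensible for
an integrated binomial likelihood.

## The synthetic-experiment generator

`fr_simulate()` reproduces the cage design — 7 densities
$\{4, 8, 16, 32, 64, 128, 256\}$ × 10 replicates per treatment cell, 24-h
exposure, aggregate vs uniform prey distributions, four enemy treatments —
with `killed ~ Binomial(N0, Ne/N0)` around the Rogers expectation. That
observation model is *exactly* the likelihood the ML fit maximizes, a
deliberate choice: parameter-recovery tests then measure the estimator,
not model misspecification. Two things follow:

* The prey-distribution treatments are encoded purely as different
  $(a, T_h)$ per cell, as the reference estimates imply; no spatial patch
  geometry is simulated, because none of the downstream statistics uses
  patch coordinates. Paired-enemy cells are generated independently per
  enemy with their own parameters; no interference term is simulated.
* Each treatment cell draws from its own random stream derived from the
  master seed and the cell labels, so adding a cell never perturbs
  another cell's data.

`fr_simulate_process()` is the deliberate *mis*specification stressor: a
mechanistic renewal process (exponential search times at rate $a n$,
fixed handling, depletion at each capture, hard clock) whose mean tracks
the deterministic Rogers solution within a few percent but whose
dispersion is not binomial. `fr_simulate_type3()` makes the attack rate
rise linearly with density to produce sigmoidal data for testing the type
screen, and `fr_simulate_olre()` generates from the GLMM's own
logistic-normal model.

**What the generator does not emulate — and what that means for the
band-overlap comparison.** Real foragers differ from one another;
published interval widths in this literature imply substantially
extra-binomial variation (the very reason the observation-level random
effect is standard there). Pure binomial noise at 70 trials yields
bootstrap intervals roughly 2.5× narrower than such published intervals.
Consequently, simulating two treatments whose generating curves differ
everywhere (e.g. the two single-predator cells) produces bands that are
disjoint over the *entire* density range: the qualitative published
pattern — separation at intermediate densities with overlap at both
extremes — depends on the wider, overdispersed bands of real data and
does not emerge under the binomial generator. The package reports this
honestly rather than inflating the generator's noise to match: passing
recovery tests demonstrate estimator correctness under the assumed
observation model, not the field-data band geometry. Users analysing real
assays get the real data's dispersion in their bootstrap automatically,
since the resampling is non-parametric.

## Validation problem sizes

The shipped test suite validates, among others: parameter recovery at all
reference cells as the mean of 20 simulated assays of 70 trials each
(recovered means are required to fall inside the published 95% CIs and
within 20% of the generating values); solver cross-agreement on a
288-point parameter grid; 90% power of the type screen over 200
simulations under each generator; percentile-interval coverage within
[90%, 99%] over 200 simulated assays at 500 resamples each; and GLMM
fixed-effect recovery within 15% over 50 simulated data sets at
$\sigma = 0.8$. These sizes were chosen to bound Monte Carlo error well
below the tolerances being asserted while keeping the full suite
comfortably runnable on a laptop.

## Known limitations

* Type II only: no flexible-exponent or Beddington–DeAngelis fitting; the
  type III generator exists solely to exercise the screen.
* The GLMM supports exactly one random-effect structure (observation-level
  intercept) and the binomial family; nested or crossed designs belong in
  `lme4`/`glmmTMB`.
* Percentile (not BCa) bootstrap intervals; with 70 trials and a smooth
  estimator the difference is small, but strongly skewed small-sample
  situations may warrant more.
* The band-overlap report is pointwise and descriptive; it is not an
  equivalence test and carries no family-wise error control.
* Printed GLMM coefficient tables from the motivating literature are not
  reproduction targets: their density coefficients are not consistent
  with raw-count logit slopes over densities up to 256 (an unstated
  transform or scaling is likely), and some rows pair $|t| \approx 1$
  with $p < 0.001$. The package reports its own internally consistent
  Wald table instead.
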