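---
title: "Spatial gender-age-period-cohort models for small-area mortality"
author: "gapcmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial gender-age-period-cohort models for small-area mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapcmap)
```

## The model

`gapcmap` fits hierarchical Bayesian models for mortality counts laid out
on a gender x area x age-group x period grid.  Conditional on the rate
$r_{gait}$, the death count in gender $g$, area $a$, age group $i$ and
period $t$ is Poisson with the person-time at risk as offset:

$$C_{gait} \mid r_{gait} \sim \mathrm{Poisson}(\mu_{gait} = n_{gait}\,
r_{gait}), \qquad \log \mu_{gait} = \log n_{gait} + \log r_{gait},$$

and the log rate decomposes additively:

$$\log r_{gait} = \beta_g + \alpha_{tg} + \gamma_{ig} + \kappa_{kg} +
\phi_a + \delta_{at}.$$

Here $\beta_g$ is a gender-specific intercept; $\alpha_{tg}$, $\gamma_{ig}$
and $\kappa_{kg}$ are gender-specific period, age and birth-cohort curves;
$\phi_a$ is a spatially structured area effect shared across genders; and
$\delta_{at}$ is a space-time interaction, also shared.  With age
intervals $M$ times wider than period intervals (five-year age groups and
annual periods give $M = 5$), the cohort of a cell is indexed by
$k = M(I - i) + t$, where age groups are ordered youngest first so that
$i = I$ (the oldest group, e.g. 85+) in the first period maps to cohort
$k = 1$.  The grid carries $K = M(I-1) + T$ cohorts; cells sharing a
cohort index lie on generalised diagonals with $\Delta t = M\,\Delta i$.
The cohort index is also mapped to an approximate birth-year interval for
labelling, but only the index enters any computation.

### Priors

* **Period, age and cohort curves**: intrinsic random walks.  The prior
  precision is $\tau D_d^\top D_d$ with $D_d$ the $d$-th difference
  operator.  The package defaults to a first-order walk for the period
  effect and second-order walks for age and cohort.  RW2 is the standard
  choice for smooth age and cohort curves in multivariate APC modelling
  (it leaves linear trends unpenalised, so slopes are informed by data
  alone); the order of each walk is exposed in `model_spec()` because
  nothing in the model forces this choice and it materially affects
  smoothing.
* **Spatial effect**: the intrinsic CAR (Besag) prior with precision
  $\tau_\phi (D - W)$, the graph Laplacian of the area adjacency graph —
  each area is conditionally centred on the mean of its neighbours.  Its
  rank is $A - c$ with $c$ connected components.
* **Space-time interaction**: the four Knorr-Held types, built as
  Kronecker products of structured/unstructured space and time precisions
  (time structure fixed to RW1): type I $I_A \otimes I_T$, type II
  $I_A \otimes Q_t$, type III $Q_s \otimes I_T$, type IV
  $Q_s \otimes Q_t$.  Ranks multiply across factors.
* **Precisions**: penalised-complexity (PC) priors by default, i.e. an
  exponential prior on the standard deviation $\sigma = \tau^{-1/2}$
  calibrated by $P(\sigma > u) = \alpha$; this induces
  $\pi(\tau) = \tfrac{\lambda}{2}\tau^{-3/2} e^{-\lambda \tau^{-1/2}}$
  with $\lambda = -\log(\alpha)/u$.  Defaults are $u = 1$, $\alpha = 0.01$
  for every precision — a weak statement that effect standard deviations
  on the log-rate scale rarely exceed 1.  A uniform-on-$\sigma$ prior is
  provided for sensitivity analysis; it is bounded above at
  $\sigma_{\max} = 100$ so the posterior is proper for any dataset (a
  deliberate, documented softening of the fully improper uniform).
* **Intercepts**: $\beta_g \sim N(0, 1000)$.

### Identifiability

Sum-to-zero constraints are applied to every non-intercept effect: each
gender's period, age and cohort curve sums to zero, $\phi$ sums to zero
within each connected graph component (on the connected study graphs this
is the single global constraint), and $\delta$ carries the family matching
its Knorr-Held kernel — a global sum for type I, per-area sums for type II,
per-period sums for type III, and both families (rank $A + T - 1$) for
type IV.

The classical APC linear-trend aliasing (cohort = period − age) is
deliberately **not** removed by additional drift constraints: the
constraint system is exactly the sum-to-zero family.  Consequently
individual curve slopes are only weakly identified (through the
random-walk priors), and the quantities this package reports as scientific
output — fitted rates, rate profiles, $e^{\phi_a}$, $e^{\phi_a +
\delta_{at}}$, cohort rate ratios — are functions of the linear predictor
that are invariant to the aliased direction.  The sampler handles the
resulting flat ridge explicitly (below).

## Inference

Re-implementing the posterior computation rather than delegating it keeps
every ingredient testable against small oracles.  The sampler is
Metropolis-within-Gibbs over three kinds of latent blocks:

* one **gender block** per gender, holding $(\beta_g, \alpha_{\cdot g},
  \gamma_{\cdot g}, \kappa_{\cdot g})$ jointly;
* the **spatial block** $\phi$; and
* the **interaction block** $\delta$.

Each block update runs a constrained Newton iteration to the mode of the
block's full conditional (the Poisson likelihood Hessian is diagonal per
effect and cheap cross-products give the within-block couplings), then
proposes from the Gaussian approximation at that mode.  Constraints are
imposed by conditioning-by-kriging on every proposal — the draw is
projected onto the constraint manifold under the proposal metric and the
proposal density is the corresponding conditional Gaussian — so every
retained draw satisfies the constraint system to machine precision, not
merely after post-hoc centring.  Updating each gender's intercept and its
three curves in a single block matters: their posterior correlation is
strong, and separate updates mix through it an order of magnitude more
slowly.

Precisions are updated by an independence Metropolis step from the matched
Gamma kernel (the full conditional is $\tau^{m/2} e^{-\tau q/2}\pi(\tau)$
with $m$ the effective GMRF dimension and $q$ the prior quadratic form, so
the acceptance ratio reduces to the prior ratio), interleaved every third
iteration with a joint move that proposes a new $\tau$ *and* re-proposes
its effect blocks at the new value — the "one-block" strategy that breaks
the amplitude-precision correlation.

Two families of **likelihood-invariant ridge moves** interweave the flat
directions: (i) the APC move tilts $\alpha$ linearly while countertilting
$\kappa$ and $\gamma$ (and shifting $\beta_g$ by the leftover constant) so
the linear predictor is unchanged cell-by-cell; (ii) exchange moves
between $\phi$ or $\alpha$ and an unstructured interaction's area/period
margins, applied only for the interaction types whose constraint systems
they preserve.  Their acceptance involves only the priors, and their step
sizes adapt during warmup (target 0.44), as does the joint-move step
(target 0.25).  Warmup begins from a deterministic coordinate sweep to the
conditional modes, which keeps the mode-centred independence proposals in
their region of validity from the first iteration.

### Numerical choices

* Kernel and rank decisions for structure matrices use a relative
  eigenvalue threshold of $10^{-8}$ times the largest eigenvalue.
* The Newton iteration stops when the largest coordinate change falls
  below $10^{-6}$ (at stationarity it converges in 2–4 steps); Cholesky
  factorisations retry with escalating jitter before failing.
* The linear predictor is clamped at 27 inside proposal curvature
  computations (a Poisson mean of $5\times10^{11}$) to avoid overflow;
  precisions are bounded above at $10^{10}$ (effect standard deviations
  below $10^{-5}$ are indistinguishable from zero on the log-rate scale).
* Degenerate inputs are rejected early: zero or negative person-time is an
  error (the offset is $\log n$), empty cohort levels (possible when
  $T < M$) simply contribute no likelihood and are smoothed by the prior,
  and a non-finite likelihood at initialisation aborts with a diagnostic.

Defaults are 2 chains and 2000 iterations with half discarded as warmup;
chains are seeded deterministically from the user seed, so results are
bit-reproducible given `(seed, chains, iterations)`.

## Reported summaries

All summaries are deterministic functions of the stored draws (rereading a
saved bundle reproduces them bit-identically): average rate profiles by
age, cohort and period; per-area posterior medians of $e^{\phi_a}$ with
exceedance probabilities $P(e^{\phi_a} > 1)$; the space-time surface
$e^{\phi_a + \delta_{at}}$ (medians taken after transformation, which for
a median is equivalent either way); region-to-national cohort rate ratios;
and per-age-group rate trajectories against period or cohort.

"Average rates" over a margin are **population-weighted** means of the
posterior-median cell rates (weights $n_{gait}$), so the national profile
equals total expected deaths over total person-time at each level; an
unweighted alternative is available via `weighted = FALSE` since the
choice is a genuine modelling decision, not forced by the model.

Directly standardised rates use the 2013 European standard population.
Because the model covers ages 25+ only, the shipped weights are the ESP
2013 values for the thirteen groups from 25–29 upward (the open-ended 85+
group takes the 85–89 and 90+ weights combined), renormalised over those
groups.  Standardised levels are therefore "per 100,000 aged 25+ standard
population" and are not comparable with all-ages ASRs — a difference of
about a factor $1/0.725$ in the weights' mass.

## The synthetic-data generator

Real register data for this class of analyses are not redistributable, so
the generator produces datasets with the statistical structure the model
assumes, and the test suite quantifies recovery on them.  The `"spain"`
preset matches the study's dimensional structure: 2 genders, 50 areas on a
5 x 10 rook lattice (one node per province; the real provincial adjacency
is deliberately not reproduced), 13 five-year age groups from [25,30) to
[85,+), 24 annual periods (labelled 1990–2013), hence 84 cohorts.

Default truth curves aim at weakly realistic magnitudes: a log-scale age
curve rising linearly and plateauing over the oldest quarter of groups
with a span of 4 log units (a factor of about 55 between the youngest and
oldest groups); a period slope of +0.005 per year; a smooth cohort hump of
amplitude 0.1; one ICAR draw rescaled to standard deviation 0.2 for
$\phi$; an unstructured interaction of standard deviation 0.05; and
baseline rates of 13 and 17 per 100,000 for females and males, bracketing
an overall crude mortality near 15 per 100,000.  Populations are drawn
once per (area, age group) around a scale of 20,000 person-years per cell
(the order of magnitude implied by roughly 700 million person-years spread
over a 50 x 13 x 24 x 2 grid) and reused across periods and genders with
±5% jitter, echoing demographic stability.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: real adjacency topology and population
geography, the ICD-9 to ICD-10 coding transition (the data model treats
the series as homogeneous, since nothing in the modelled structure
distinguishes the eras), migration, age heaping, late registration, or
overdispersion beyond Poisson.  Recovery results speak to the correctness
of the implementation under the model's own assumptions, not to the
model's adequacy for any particular registry.

## Problem sizes used by the tests

The checks in `tests/testthat` and `scripts/acceptance.R` run on reduced
configurations chosen to keep a full run comfortable on a single CPU: a
`"reduced"` preset (15 areas on a 3 x 5 lattice, 6 age groups, 10 periods;
1,800 cells) for recovery, sensitivity and benchmark fits, and a `"toy"`
preset (9 areas, 4 age groups, 6 periods) for model-comparison
replications.  Recovery studies use 20 replicates with single-chain fits
of 500 iterations; the small-scale oracles (a 1-D grid posterior and a
6-scalar importance-sampling reference) use longer chains since the models
are tiny.  These sizes are the package's own benchmark definitions; all of
them scale up by changing `gapc_preset()` or passing larger `iterations`.

## Known limitations

* The sampler is designed for the moderate latent dimensions of
  area-level APC models (hundreds to a few thousand latent scalars);
  the dense per-block factorisations would need sparse-matrix
  replacements for very large graphs.
* Gender-specific curves may share a precision (default) or not, but
  genders are not smoothed jointly — no cross-gender correlation prior.
* Only sum-to-zero identifiability constraints are implemented; users who
  want drift-identified curve slopes must impose their own convention
  downstream.
* WAIC and DIC are the only comparison criteria; no cross-validation.
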