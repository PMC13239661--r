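---
title: "Designing tracking studies by simulation: models, estimators and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tracking studies by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trackdesign)
```

This vignette documents the statistical machinery inside `trackdesign`:
the movement model and its closed-form summaries, the fitting and
uncertainty conventions, the two target estimators, the hierarchical
population model, and the design-evaluation loop — together with the
numerical choices that were genuinely open and why they were settled the
way they were.

## The movement process

Each individual moves as an isotropic, stationary Gaussian process, per
axis one of:

* **IID** — positions uncorrelated around a center; parameters: per-axis
  positional variance $\sigma$ (m²).
* **OU** — Ornstein–Uhlenbeck position process; adds the position
  autocorrelation timescale $\tau_p$ (s), the home-range crossing time.
* **OUF** — OU with correlated (foraging-like) velocities; adds the
  velocity autocorrelation timescale $\tau_v$ (s), with
  $\tau_p \ge \tau_v > 0$.

The OUF positional autocovariance is
$C(t) = \sigma(\tau_p e^{-t/\tau_p} - \tau_v e^{-t/\tau_v})/(\tau_p-\tau_v)$,
with the analytic repeated-root limit
$C(t) = \sigma e^{-t/\tau_p}(1 + t/\tau_p)$ used when
$|\tau_p-\tau_v| < 10^{-6}\tau_p$ for numerical stability. The stationary
velocity variance is $\sigma/(\tau_p\tau_v)$ per axis, whence the 95%
home-range area $A = \pi q_{0.95}\sigma$ ($q_{0.95}$ the $\chi^2_2$
quantile) and the mean speed
$E[v] = \sqrt{\pi\sigma/(2\tau_p\tau_v)}$ (the Rayleigh mean). These
closed forms are the "truths" that every design evaluation scores
against; under population heterogeneity (log-normal parameter
distributions) their population means are also closed-form
(`trueArea(pop)`, `trueMeanSpeed(pop)`), so no Monte-Carlo truth is
needed.

**Exact simulation.** Per axis the OUF process is the 2-state
(position, velocity) Gaussian Markov process whose dynamics matrix has
eigenvalues $-1/\tau_p$ and $-1/\tau_v$. Transitions over a step are the
matrix exponential and the innovation covariance follows from the
stationary-covariance identity $Q = S - \Phi S \Phi^\top$, so simulation
at arbitrary (including irregular) times is exact and $O(n)$ — the test
suite checks distributional equality against draws from the dense
closed-form covariance matrix.

**Units and seeds.** Everything internal is SI (meters, seconds).
User-facing durations accept strings (`"2 months"`); the calendar
conventions are fixed at 1 month = 30.4375 d and 1 year = 365.25 d.
Every stochastic operation takes one integer seed; multi-individual
operations derive per-individual sub-seeds by the documented contract
`subSeed(seed, i) = (seed + 1000003 i) mod (2^31-1)`, so a population
simulation is reproducible individual by individual.

## Fitting and effective sample sizes

Candidate models (IID, OU, OUF) are fitted by maximizing the exact
Gaussian likelihood, evaluated in $O(n)$ by a Kalman filter over the
per-axis state space, with the observation-error variance (if any) added
to the measurement equation. Three conventions matter:

* **The center is profiled out by GLS inside the filter.** The filter is
  run jointly on the observations and on a constant regressor; the
  innovations decomposition yields the generalized-least-squares center
  and the profile likelihood at no extra cost. This keeps the
  optimization over log-parameters only (1–3 dimensions) and is stable
  even when the duration barely exceeds the crossing time.
* **Point estimates are profile-ML; uncertainty is REML.** Confidence
  intervals and effective sample sizes come from the curvature of the
  *restricted* likelihood at its own optimum, which accounts for the
  information spent estimating the center: for IID data the area
  effective sample size is then exactly $n-1$, and for OU data it scales
  as $T/\tau_p$ (about 9–10 effective locations for a 10-day track with a
  1-day crossing time). The restricted surface can lose its interior
  optimum when $T \sim \tau_p$ (only the diffusion rate
  $\sigma/\tau_p$ is then identified); in that regime the curvature is
  taken at the ML estimates instead. Point estimates stay profile-ML
  because restricted *estimation* diverges on that same ridge, and
  because the resulting short-duration underestimation of $\sigma$ is the
  real behavior a study-design tool must reproduce. Wald intervals for
  the log-parameters are centered at the restricted-likelihood estimates
  (the point where the curvature is taken), which removes most of the
  downward bias of the timescale estimates.
* **Effective sample sizes.** The area estimate is treated as
  $\chi^2_\nu$-distributed with $\nu = 2(\hat\sigma/SE(\hat\sigma))^2
  = 2/\mathrm{Var}(\log\hat\sigma)$ and $N_{area} = \nu/2$ (capped at
  $n$); $N_{speed}$ is defined analogously from the log velocity-variance
  information through the delta method (0 for non-OUF fits). This
  convention reproduces both anchor cases above; its higher-order terms
  are a package convention, documented here because no printed standard
  exists.

Model selection uses AICc on the profile likelihood with parameter counts
3 (IID), 4 (OU), 5 (OUF) — isotropic variance, timescales, and the
two-dimensional center — on $2n$ observations; ties below $10^{-6}$ go to
the simpler model. Multi-start Nelder–Mead (default 4 deterministic
starts) is initialized from the empirical semivariogram at lags
$\Delta t$ (short-lag expansion gives $\tau_v$) and $T/4$ (gives
$\tau_p$); optimization is over logs, so the OUF likelihood's symmetry in
its two timescales is resolved by sorting afterwards. A track whose
second differences vanish (deterministic, straight-line motion) is
rejected before fitting with an explicit error.

## Home-range area

`akdeArea()` is a kernel density estimate over the observed locations
whose per-axis Gaussian reference bandwidth variance is
$h^2 = \hat\sigma N_{area}^{-1/3}$ — the defining idea of
autocorrelation-informed kernel density estimation: the bandwidth shrinks
with the *effective*, not nominal, sample size. The 95% highest-density
region is found on a 151×151 grid spanning the fitted center ±
$4\sqrt{\hat\sigma + h^2}$ (grid-halving changes the area by <1% in
tests), with fractional counting of the boundary cell.

The raw highest-density-region area of a kernel mixture is biased: the
kernels add variance $h^2$, and the observed points under-disperse
relative to the stationary law because they are autocorrelated. Under
the Gaussian reference, the expected raw area is
$(1 - \kappa + N_{area}^{-1/3})$ times the target, where $\kappa$ is the
mean pairwise positional correlation of the sampled times under the
fitted model (computed in $O(n)$ on the regular-grid approximation). The
estimator divides by this factor. The residual bias is that of
$\hat\sigma$ itself: strongly negative when $T$ is a small multiple of
$\tau_p$ and shrinking monotonically towards zero as $T/\tau_p$ grows —
the test suite verifies the sign and the monotone decrease across
$T/\tau_p \in \{2, 8, 32\}$ and agreement with the truth to within a few
percent by $T = 64\tau_p$. Short tracking durations underestimate home
ranges, and no population sample size compensates for that. Higher-order small-sample
debiasing of the kind practiced in the reference ecosystem is out of
scope; the first-order calibration above is the package's own choice.
Confidence intervals scale the point estimate by
$\chi^2_{\nu}$ with $\nu = 2N_{area}$; an IID selection falls back to a
classical KDE with the nominal $n$ and flags the estimate, and
$N_{area} < 2$ flags it as unreliable.

`gaussianArea()` is the model-based shortcut $\pi q \hat\sigma$ with the
same interval convention; it agrees with the kernel estimator to within
10% on average at $N_{area} \ge 50$.

## Mean speed

`ctsdSpeed()` estimates the mean speed by conditional simulation:
velocities are drawn from the conditional (kriging) distribution of the
fitted OUF state space given the observed locations, using the exact
Gaussian-conditioning identity
$v_{cond} = E[v\,|\,y] + (v_{sim} - E[v\,|\,y_{sim}])$ with a
Rauch–Tung–Striebel smoother supplying the conditional means. The mean
modulus over the track span, averaged over `nDraws = 200` conditional
draws (the Monte-Carlo error of the mean is far below parameter
uncertainty at 200), is the estimate. The interval combines parameter
uncertainty ($\chi^2$ with $\nu = 2N_{speed}$) with the conditional-draw
dispersion through an effective degrees-of-freedom
$\nu_{eff} = 2/(1/N_{speed} + \mathrm{Var}(draws)/(n_{draws}\cdot
value^2))$.

When model selection does not retain correlated velocities (sampling
coarser than about $3\tau_v$ loses the statistical signature of
directional persistence), the estimate *fails* with an explicit reason;
the design loop counts these failures and never imputes them. The naive
straight-line-displacement estimator `sldSpeed()` is provided as the
reference foil: under uncorrelated location error its expectation grows
without bound as the interval shrinks (a stationary animal with error RMS
$r$ per axis yields $\sqrt{\pi} r$ of spurious displacement per step),
while the conditional-simulation estimator models the error instead.

## Population-level inference

Individual estimates of a positive quantity are treated as
$\chi^2_{\nu_i}$-distributed. On the log scale this gives a known
sampling bias $E[\log(\chi^2_\nu/\nu)] = \psi(\nu/2) - \log(\nu/2)$ and
variance $\psi'(\nu/2)$; `popMean()` subtracts the bias, then fits the
normal–normal hierarchical model
$y_i \sim N(\mu, s_i^2 + v)$ by maximum likelihood with $v \ge 0$
(boundary $\hat v = 0$ is legitimate — a homogeneous population), the
weights $1/(s_i^2+\hat v)$ realizing the downweighting of uncertain
individuals. The population mean is the log-normal back-transform
$e^{\mu + v/2}$. The 95% interval profiles the *log population mean*
$\xi = \mu + v/2$ directly (inner maximization over $v$, $\chi^2_1$
cutoff 3.841): profiling $\mu$ alone and plugging $\hat v$ ignores the
uncertainty of $\hat v$ and measurably undercovers at moderate $m$, so
the profile is taken on the quantity actually reported. With $m = 1$ the
single estimate is returned with its own $\chi^2$ interval and flagged.

`popMeanIG()` is the alternative population law: true values
inverse-Gaussian, $\chi^2$ sampling kernels, marginal likelihood by
quadrature on the log scale over the union of the kernel and population
supports (the kernel can be much sharper than the population; integrating
on the original scale misses it). It agrees with the normal–normal fit
when between-individual variance is negligible and falls back to it (with
a warning) on non-convergence or $m < 3$.

`popAverageModel()` applies the same machinery to each log-parameter of a
set of fits, with per-parameter $\nu_i = 2/\mathrm{Var}(\log\hat\theta_i)$
from the fit information, yielding a `PopulationModel` (means + diagonal
between-individual covariance) that can seed new simulations — the
pilot-data path of the workflow. The package treats each scale parameter
univariately on the log scale; the full matrix-logarithm treatment of
anisotropic covariance structures is a documented non-goal.

## Deployment hazards and the design loop

`corruptTrack()` applies hazards in their physical causal order:
premature permanent failure (exponential failure time with the given
hazard rate), then the storage cap (earliest fixes kept), then Bernoulli
fix-success thinning, then additive iid Gaussian location error per axis
(optionally scaled by per-fix multipliers), recorded on the track so that
fitting can model it. A deployment reduced below 2 usable fixes is an
*outcome* (counted), not an error.

`evaluateDesign()` runs the full loop per replicate: draw $m$ individuals
from the population model, simulate at the schedule, corrupt, fit,
estimate the targets, pool with `popMean()`, and express the result as a
relative error ($100(\hat\theta - \theta)/\theta$; negative =
underestimation) against the closed-form population truth. The verdict
for a target is a conjunction: the mean relative error *and* both
confidence bounds of the mean must lie within the threshold (default
±5%). Sensitivity analyses: `resampleCombinations()` enumerates all
combinations of $m$ individuals when there are at most 250, otherwise
samples 250 distinct combinations uniformly (rejection on a canonical
sorted-tuple key); `looCorrectness()` recomputes the population mean
leaving each individual out once and reports the percentage of
leave-one-out estimates within the threshold. Everything is seeded
through the sub-seed contract, so identical `(pop, design, seed)` give
bit-identical reports.

## What the generator does and does not emulate

The synthetic tracks are exactly stationary, isotropic, and
single-regime: no behavioral switching, migration, dispersal, boundary
effects, anisotropic ranges, or autocorrelated location error. Passing
tests therefore demonstrate that the *estimation pipeline* is calibrated
under its own assumptions and that the design rules (duration governs
area information, interval governs speed information, population size
governs precision) follow quantitatively; they do not certify performance
on data violating stationarity or isotropy — real pilot data should be
segmented to a range-resident regime before parameter extraction.

## Problem sizes and numerical defaults

The shipped tests use tracks of roughly 50–2000 fixes, populations of
2–25 individuals, and 10–300 replicates per experiment — enough for the
Monte-Carlo standard errors each assertion states, while keeping the full
suite in the minutes range on one CPU. Numerical defaults: optimizer
tolerance $10^{-10}$ (relative) with 4 deterministic starts; AKDE grid
151×151; 200 conditional draws for speed; profile-likelihood cutoff
3.841; simulation hard cap $10^6$ fixes per track; repeated-root switch
at $10^{-6}\tau_p$. The command-line interface (`inst/cli/trackdesign`)
and the YAML project configuration cover the same functionality as the R
interface; unknown configuration keys are errors by design.

## Known limitations

Short-duration area estimation remains negatively biased (by
construction, matching the behavior of the field's estimators);
restricted-likelihood effective sample sizes are reported as 0 with a
warning when the information matrix is singular; the inverse-Gaussian
population fit relies on numerical quadrature and reverts to the
normal–normal estimator when it cannot converge; and geographic handling
is limited to the local azimuthal-equidistant projection about a dataset
centroid (spherical model), adequate below a few hundred kilometers of
extent.
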