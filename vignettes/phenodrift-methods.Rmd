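---
title: "Models and methods in phenodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phenodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodrift)
```

# Overview

Individuals drawn from the same genotype and environment still differ in
behavior, and each individual's behavioral bias also wanders over its own
lifetime. `phenodrift` separates and quantifies these two sources of
variability — developmental **bet-hedging** (the spread of phenotypes fixed
at birth, written $\sigma_{B}$) and **phenotypic drift** (random daily
change of an individual's phenotype, written $\sigma_{D}$) — and then asks
when each is adaptive in a fluctuating environment. The package contains
three layers:

1. *Measurement*: kinematic classification of circling direction in arena
   tracks, turning-index binning, Blackman low-pass filtering, and
   Lomb–Scargle spectra for gappy series.
2. *Inference*: a hierarchical Bayesian AR(1) model of daily turn bias that
   decomposes panel variability into $\sigma_B$, $\sigma_D$ and a
   persistence parameter $\varphi$.
3. *Theory*: an analytically solvable phenotype-switching model, a
   deterministic age-structured population simulator on a binned preference
   axis, and fitness-landscape sweeps with cross-landscape PCA.

# The hierarchical AR(1) bias model

For fly $i$ in group $g$ on day $t$, the latent mean-centered bias follows

$$x_{i,1} \sim \mathcal N(0, \sigma_{B,g}^2), \qquad
  x_{i,t} = \varphi_g\, x_{i,t-1} + \mathcal N(0, \sigma_{D,g}^2).$$

An observed right fraction $R_{i,t}$ from $n$ scored turns enters as
$R_{i,t} - 0.5 = x_{i,t} + e_{i,t}$ with binomial sampling noise
$e_{i,t}$. $\varphi = 1$ is a pure random walk; $\varphi = 0$ a memoryless
reversion to the unbiased state; all estimates reported on the fraction
scale (bias units are deviations of a fraction from 0.5).

Priors are weakly informative: Inverse-Gamma(3, 1) on each scale (on the
scale itself, not the variance) and $\mathcal N(0, 10)$ (variance 10,
untruncated) on $\varphi$. Groups are fit independently (no pooling of
genotype-level parameters), with flies nested within group.

**Sampler.** The posterior is explored by a blocked Gibbs sampler written
for this model:

* latent trajectories by forward-filter backward-sampling (FFBS),
  vectorized across flies; days without an observation simply contribute no
  measurement update, which is the marginalized equivalent of treating the
  missing observation as a latent quantity under a diffuse prior;
* $\varphi$ by its conjugate Normal full conditional;
* $\sigma_B$ and $\sigma_D$ by univariate slice sampling on the log scale
  (the Inverse-Gamma-on-the-scale priors are non-conjugate).

Default configuration: 4 chains, 1000 warmup draws, 2000 retained draws,
overdispersed starting points per chain. Convergence is gated at split
$\hat R \le 1.05$ and ESS $\ge 400$ per reported parameter (via `coda`);
failures warn and flag the result rather than erroring, because short
exploratory runs legitimately trip the ESS gate.

**Observation variance.** In counts mode the binomial noise variance is
moment-matched as $\hat p_i(1-\hat p_i)/n_{i,t}$ with $\hat p_i$ the fly's
*pooled* mean fraction. A per-day plug-in
$\hat p_{i,t}(1-\hat p_{i,t})/n$ is subtly biased: near $p = 0.5$,
$\hat p(1-\hat p) \approx 0.25 - e^2$, so days with large realized sampling
error are assigned *smaller* variance, the filter over-trusts exactly the
noisiest observations, and $\sigma_D$ inflates by a couple of percent —
enough to push 95% credible intervals systematically off a small truth.
The fly-level estimator removes the correlation. In direct mode the
centered fraction is treated as the latent bias up to negligible error
(variance $10^{-10}$), which is appropriate for synthetic panels generated
without an observation layer.

**Validation.** Because the latent trajectories are jointly Gaussian, the
complete-data marginal likelihood of a gap-free panel is multivariate
normal with an analytic AR(1) covariance. The test suite integrates
likelihood × prior over a 3-D parameter grid and compares posterior means
with the Gibbs output on identical data; they agree to about $10^{-4}$.
Parameter recovery at the reference conditions (200 flies × 9 days,
$\sigma_B = 0.10$, $\sigma_D = 0.05$, $\varphi = 0.8$, 500 turns/day)
covers all three truths in ≥ 90% of seeded replicates.

**Group comparisons.** The `q`-value for a parameter difference is the
minimum posterior probability that the difference is ≤ 0, evaluated over
all cross-pairs of draws with ties counted one half (the Mann–Whitney
statistic). Identical draw sets give exactly 0.5; disjoint sets are
censored below the draw resolution and printed as `q < resolution`.

# The synthetic panel generator

`gen_daily_bias()` runs the same AR(1) process generatively: latent biases
start at $\mathcal N(\mu, \sigma_B^2)$, evolve with persistence $\varphi$
and innovation $\sigma_D$, and are observed as binomial samples with the
success probability $x + 0.5$ clipped to $[0.01, 0.99]$ (the clip only
matters for extreme parameter draws). A global seed fans out into per-fly
substreams, so fly $i$'s data do not depend on how many flies are
requested. Missing days are i.i.d. Bernoulli by default; a preset
weekly-assay mask (`assay_day_mask()`, three days per week for three
weeks) mirrors a realistic panel cadence.

What the generator deliberately does *not* emulate: circadian or
photoperiod structure in activity, activity-dependent turn counts (every
fly-day has the same `turns_per_day`), and missingness correlated with
behavior. Tests passing on these panels therefore validate the estimator
under its own assumptions, not robustness to behavioral confounds of real
assays.

`gen_circular_walk()` (a biased angular random walk on an annulus) and
`gen_gappy_series()` (FFT-synthesized $1/f^\alpha$ noise with contiguous
block gaps) exist to exercise the kinematics and spectral code with known
ground truth; they make no pretense of fly locomotor realism beyond the
sign and persistence structure those tests need.

# Kinematics and spectra

Displacements are decomposed about the arena center; a displacement is
`stationary` below a speed floor (default 1 mm/s), `radial` when the radial
component dominates the tangential one (threshold ratio 1), else `CCW`/`CW`
by the tangential sign. Neither threshold has a canonical published value;
both are exposed as arguments. The turning index per time bin is
$(N_{CCW} - N_{CW})/(N_{CCW} + N_{CW})$, a signed circling fraction in
$[-1, 1]$, missing where a bin has no directional counts.

The low-pass filter is a Blackman-tapered weighted moving average with a
51-hour window, renormalizing weights over non-missing samples per window
and returning missing where less than 25% of the window weight is present
(the coverage floor keeps gap edges from being dominated by a handful of
samples). The Lomb–Scargle periodogram uses the classical phase-offset
form; on an evenly sampled series its value at a Fourier frequency equals
the classical periodogram $|FFT|^2/n$ exactly, which the tests assert to
$10^{-6}$. Mean spectra carry pointwise percentile bootstrap intervals
(resampling whole series, default 1000 resamples). The shuffle control
permutes values among non-missing timestamps, exactly preserving the
marginal; on persistent series it flattens low-frequency power, the
separation used to demonstrate that slow drift is real structure.

# The two-state switching theorem

An environment flips state with probability $p$ per period; a fraction $f$
of the population switches phenotype; matching the environment yields
fitness $w_{A}$ or $w_{B}$, mismatching is lethal. The per-period expected
log growth is

$$G(f) = p\log f + (1-p)\log(1-f) + \mathbb E_\pi[\log w],$$

with $\pi$ the stationary environment distribution. The fitness term is an
additive constant, so the unique maximizer is $f^* = p$ regardless of
$(w_A, w_B)$ — randomizing phenotype in proportion to environmental
turnover is a proportional-betting result. The N-state generalization with
transition matrix $P$, strategy matrix $S$ and fitness vector $w$ has
growth $\sum_i \pi_i \sum_j P_{ij}\log(S_{ij} w_j)$; rows decouple and the
optimum is $S^* = P$ for every positive $w$. Tests verify both by
brute-force grid search (step $10^{-3}$ over $f$; resolution-0.02 simplex
grids per row of $S$) and by Monte-Carlo simulation against the closed
form. The continuous-state case is represented by the N-state model at
fine discretization rather than by a separate functional treatment.

# The age-structured population simulator

The population is a deterministic density $n_{\phi, \alpha, t}$ over 200
preference bins on $[-1, 1]$ and integer ages $\alpha \le 10 + 2a_{\min}$
days. Each day, in order:

1. **drift** — every age class's preference distribution is convolved with
   a Gaussian kernel of s.d. $\sigma_D$, column-renormalized at the domain
   boundaries so mass is conserved exactly;
2. **survival** — multiplication by
   $\exp\!\big(-(\phi - E_t)^2 / 2\sigma_e^2\big)$, the Gaussian penalty of
   mismatch with the day's environmental optimum $E_t$
   ($\sigma_e = 0.125$ by default);
3. **bounding** — multiplication by
   $\exp\!\big(-(\phi - \mu_{env})^2 / 2\sigma_{max}^2\big)$
   ($\sigma_{max} = 3$), the envelope that stops preferences diffusing
   indefinitely and supplies the mean reversion seen in fitted $\varphi$;
4. **aging** — ages increment; individuals past the maximum lifespan are
   removed;
5. **births** — an age-0 cohort of mass $\beta$ (default 40) times the
   total mass at ages $\ge a_{\min}$ (default 10 days), spread as
   $\mathcal N(\mu_{env}, \sigma_B^2)$ truncated-renormalized onto the
   bins.

The caption-level description of the daily update does not dictate an
order; drift → survival → bounding → aging → births was chosen so that
newborns face their first selection on their first full day of life. The
bounding term is applied as a daily multiplicative envelope by default; an
alternative reading — reversion folded into the drift kernel as a
mean-reverting (OU-type) step with stationary s.d. $\sigma_{max}$ — is
available via `bounding = "ou"`.

Total abundance is tracked in log space with per-day renormalization, so
runs of a thousand days neither overflow nor underflow; a day whose total
multiplier reaches numerical zero flags extinction ($-\infty$ log growth).
With no drift, no bet-hedging and a constant environment the model
collapses to a scalar Leslie process; the simulator matches the dominant
eigenvalue of the corresponding Leslie matrix (fecundity $s\beta$ at
mature ages, survival $s$ on the subdiagonal) to $10^{-6}$ relative, and
the finite-horizon matrix iteration exactly ($10^{-10}$).

Note one discretization detail: with an even bin count no bin is centered
at 0, so a "delta at 0" sits in the bin with midpoint $+0.005$; oracle
comparisons use that midpoint.

# Environments and landscapes

Synthetic environments are white noise band-passed with a hard frequency
mask (the filter shape is a declared convention), z-scored, and scaled to
s.d. $\sigma_{mean}$ — so amplitude and period band are controlled
independently. Real daily series are preprocessed by trimming, splitting
at missing runs longer than 5 days, linear interpolation of shorter gaps,
seeded-random greedy sampling of non-overlapping 1000-day windows (no data
point reused; the greedy order is the declared tie-break, so a 2100-day
segment may yield one window or two depending on the seed), then the same
z-score-and-scale step. Sub-daily series are first aggregated to daily
mean, maximum and minimum.

A fitness landscape evaluates the mean over an environment ensemble of the
log population fold change for each $(\sigma_B, \sigma_D)$ cell — the log
of the geometric-mean fold change; a literal geometric mean of logs would
be ill-defined because logs can be negative. Extinct cells are kept as
$-\infty$ and flagged; normalization maps finite cells to $[0, 1]$ and
extinct cells to 0. `find_optimum()` breaks ties toward the smallest
$(\sigma_B, \sigma_D)$, so "no variability" wins unless variability
strictly pays. PCA across landscapes (`stats::prcomp`, mean-centered, no
scaling) returns loadings reshaped to the grid, scores, and variance
fractions, with each component's largest-magnitude loading made positive;
whether to decompose raw or normalized landscapes is a user switch
(normalization is required whenever any cell is extinct).

## Problem sizes and regimes used in the checks

The test and acceptance workloads run at desk scale by design: recovery
uses 20 replicate panels of 200 flies × 9 days at 4 × (500 + 500) draws;
landscape direction checks use 11 × 11 grids over $\sigma_B \in [0, 0.5]$
and $\sigma_D \in [0, 0.05]$ (the ranges used for the real-series and
frequency sweeps respectively), 10-environment ensembles and 200-day runs,
with defaults $\sigma_e = 0.125$, $\sigma_{max} = 3$, $a_{\min} = 10$,
$\beta = 40$. Three regimes probe the directional structure: fluctuation
periods of 2–3 days (or amplitude 0.05) favor no variability at all;
periods of 8–12 days — about the maturation time — at amplitude 0.3 favor
drift ($\sigma_D^* > 0$); periods of 100–200 days — far beyond the 30-day
lifespan — at amplitude 1 favor bet-hedging ($\sigma_B^* > 0$). Full-scale
sweeps (1001 days, 100 environments, finer grids) use the same code paths
and are reached by changing arguments.

# Known limitations

* The observation link is a Gaussian moment-match of the binomial; at very
  small turn counts (tens of turns) an exact binomial likelihood would
  differ, and panels dominated by such days should be interpreted with
  care.
* Groups are fit independently; if genotypes share structure, partial
  pooling would sharpen estimates but is not implemented.
* The population model is a deterministic density evolution: no demographic
  stochasticity, spatial structure or genetics, so "extinction" means mass
  below numerical resolution, not a stochastic absorption event.
* $\varphi$ is estimated without truncation to $[0, 1]$; data with strong
  anti-persistence would produce negative posterior mass rather than an
  error.
* The real-series loader takes local delimited files only; it does not
  talk to any data service.
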