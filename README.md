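# phenodrift

Individuals with identical genomes reared identically still behave
differently — and each individual's behavioral bias also wanders over its
own lifetime, with no external trigger. `phenodrift` is an R package for
quantifying and theorizing about these two layers of variability:

* **bet-hedging** — the spread of phenotypes fixed at birth, measured as
  the standard deviation σ<sub>B</sub> of initial biases across
  individuals;
* **phenotypic drift** — random day-to-day change within an individual,
  measured as the innovation standard deviation σ<sub>D</sub> of a daily
  autoregressive process.

It is written for behavioral ecologists and quantitative biologists who
work with per-individual daily bias panels (e.g. *Drosophila* locomotor
handedness assays), long gappy behavioral recordings, and life-history
simulation.

## What is inside

**Inference.** A hierarchical Bayesian AR(1) model of daily turn bias: for
fly *i* on day *t*,

    x[i,1] ~ Normal(0, sigma_B^2)
    x[i,t] = phi * x[i,t-1] + Normal(0, sigma_D^2)
    R[i,t] - 0.5 = x[i,t] + binomial sampling noise

with Inverse-Gamma(3, 1) priors on both scales and a Normal(0, 10) prior
on the persistence φ. Fitting is by a blocked Gibbs sampler
(forward-filter backward-sampling for the latent trajectories) with
split-R̂/ESS convergence gates, posterior summaries, and all-pairs
posterior *q*-values for group comparisons. Missing assay days are handled
exactly, as latent states without a measurement update.

**Theory.** A closed-form two-state switching model whose optimal
phenotype-switching fraction equals the probability *p* that the
environment changes — independent of the match fitnesses — plus its
N-state generalization (optimal strategy matrix = environment transition
matrix). A deterministic age-structured population simulator evolves a
density over 200 preference bins on [-1, 1] under daily Gaussian drift,
Gaussian environment-matching survival (σ<sub>e</sub> = 0.125), a bounding
envelope (σ<sub>max</sub> = 3), maturity-gated births (β = 40 offspring
per mature individual per day, maturity a<sub>min</sub> = 10 days) and a
finite lifespan of 10 + 2·a<sub>min</sub> days. Fitness-landscape sweeps
over (σ<sub>B</sub>, σ<sub>D</sub>) across environment ensembles, optimum
extraction, and PCA across landscapes.

**Measurement and simulation utilities.** Turn-direction classification
from arena centroid tracks, turning-index binning, 51-hour Blackman
low-pass filtering tolerant of gaps, Lomb–Scargle periodograms with
bootstrap confidence bands and shuffle controls; generators for synthetic
bias panels, biased circular walks, 1/f^α gappy series, and band-limited
random environments; a loader that turns real daily climate-style series
(local delimited files) into model-ready 1000-day windows.

## Worked example

Simulate a 100-fly, 9-day handedness panel with known ground truth and
recover its parameters:

```r
library(phenodrift)

gt <- ground_truth(sigma_bh = 0.10, sigma_drift = 0.05, phi = 0.8,
                   turns_per_day = 500, seed = 7)
panel <- gen_daily_bias(gt, n_flies = 100, n_days = 9)
head(panel, 3)
#>     fly_id day n_right n_turns r_obs  group
#> 1 fly_0001   1     188     500 0.376 group1
#> 2 fly_0001   2     233     500 0.466 group1
#> 3 fly_0001   3     234     500 0.468 group1

fit <- fit_ar(panel, cfg = mcmc_config(n_chains = 4, n_warmup = 500,
                                       n_draws = 500, seed = 1))
fit
#> Hierarchical AR(1) posterior (1 group(s), 4 chains x 500 draws)
#>    group   parameter    mean    q2.5   q97.5  rhat    ess
#> 1 group1    sigma_bh 0.10365 0.08996 0.12025 1.005 1914.6
#> 2 group1 sigma_drift 0.04893 0.04590 0.05212 1.003  871.7
#> 3 group1         phi 0.83699 0.79629 0.87543 1.001 1415.0
```

All three 95% credible intervals cover the generating values: the panel's
initial spread (σ<sub>B</sub> = 0.10), its daily drift rate
(σ<sub>D</sub> = 0.05) and its persistence (φ = 0.8). The drift estimate
says a typical fly's right-turn probability moves by about five percentage
points per day, over and above binomial counting noise.

The switching theorem, numerically:

```r
f <- seq(0.001, 0.999, by = 0.001)
g <- sapply(f, function(fi)
  as.numeric(expected_log_growth(switch_model(0.25, fi, c(2, 0.5)))))
f[which.max(g)]
#> [1] 0.25
```

The growth-maximizing switching fraction equals the environmental change
probability even with strongly asymmetric match fitnesses.

A small fitness-landscape sweep (fluctuation period ≈ maturation time, so
drift should pay):

```r
envs <- lapply(1:5, function(i)
  gen_filtered_noise(c(8, 12), sigma_mean = 0.3, 200, seed = i))
L <- sweep_landscape(envs, seq(0, 0.5, length.out = 6),
                     seq(0, 0.05, length.out = 6), popsim_params())
L
#> Fitness landscape: 6 x 6 cells, 5 environments, 200 days
#> optimum: sigma_b = 0.2  sigma_d = 0.05
```

The optimum sits at a strictly positive drift rate: with the environment
fluctuating on roughly the maturation timescale, individuals that wander
in preference outgrow both frozen specialists and pure bet-hedgers.

A thin command-line wrapper over the same functions ships in
`inst/cli/phenodrift` (subcommands `gen-panel`, `env-gen`, `env-prep`,
`popsim`, `two-state`, `spectrum`, `lowpass`, `fit-ar`).

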