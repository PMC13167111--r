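# Shared fixture builders (everything generated in code at test time).

# standard recovery-truth generator settings used across AR-model tests
recovery_gt <- function(seed) {
  ground_truth(sigma_bh = 0.10, sigma_drift = 0.05, phi = 0.8,
               turns_per_day = 500L, seed = seed)
}

# continuous angle from a wrapped [-pi, pi) sequence
unwrap_angle <- function(a) {
  d <- diff(a)
  d <- ifelse(d < -pi, d + 2 * pi, ifelse(d > pi, d - 2 * pi, d))
  cumsum(c(a[1], d))
}

# evenly sampled noisy sinusoid
sinusoid_series <- function(n = 256, f0 = 0.11, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  t <- 0:(n - 1)
  data.frame(time = t, value = sin(2 * pi * f0 * t) + rnorm(n, 0, noise_sd))
}

# simple AR(1) series on a unit grid
ar1_series <- function(n = 512, phi = 0.9, seed = 1) {
  set.seed(seed)
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  data.frame(time = 0:(n - 1), value = x)
}

# band-limited random environment ensemble
env_ensemble <- function(band, sigma_mean, n_env, days, seed0) {
  lapply(seq_len(n_env), function(i)
    gen_filtered_noise(band, sigma_mean, days, seed = seed0 + i))
}

# Deterministic quadrature oracle for the AR model posterior: integrates the
# latent trajectories out analytically (the complete-data marginal is
# multivariate normal), evaluates likelihood x prior on a 3-D grid, and
# returns posterior means. Valid for complete, direct-observation panels.
ar_quadrature_means <- function(lat, priors = ar_priors(),
                                sb_range = c(0.05, 0.25),
                                sd_range = c(0.02, 0.12),
                                ph_range = c(0.1, 1.1), n_grid = 40L) {
  N <- nrow(lat); T <- ncol(lat)
  S <- crossprod(lat)
  loglik <- function(sb, sd_, ph) {
    C <- matrix(0, T, T)
    C[1, 1] <- sb^2
    for (t in 2:T) C[t, t] <- ph^2 * C[t - 1, t - 1] + sd_^2
    for (s in 1:(T - 1)) for (t in (s + 1):T)
      C[s, t] <- C[t, s] <- ph^(t - s) * C[s, s]
    ch <- tryCatch(chol(C + diag(1e-12, T)), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    -N * sum(log(diag(ch))) - 0.5 * sum(diag(chol2inv(ch) %*% S))
  }
  lprior <- function(sb, sd_, ph)
    -(priors$sigma_bh_shape + 1) * log(sb) - priors$sigma_bh_scale / sb -
    (priors$sigma_drift_shape + 1) * log(sd_) -
    priors$sigma_drift_scale / sd_ -
    (ph - priors$phi_mean)^2 / (2 * priors$phi_var)
  sbg <- seq(sb_range[1], sb_range[2], length.out = n_grid)
  sdg <- seq(sd_range[1], sd_range[2], length.out = n_grid)
  phg <- seq(ph_range[1], ph_range[2], length.out = n_grid)
  lp <- array(NA_real_, c(n_grid, n_grid, n_grid))
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid))
    for (k in seq_len(n_grid))
      lp[i, j, k] <- loglik(sbg[i], sdg[j], phg[k]) +
        lprior(sbg[i], sdg[j], phg[k])
  w <- exp(lp - max(lp)); w <- w / sum(w)
  c(sigma_bh = sum(w * array(sbg, dim(w))),
    sigma_drift = sum(sweep(apply(w, c(2, 3), sum), 1, sdg, "*")),
    phi = sum(apply(w, 3, sum) * phg))
}
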