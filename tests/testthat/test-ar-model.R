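test_that("prior and config constructors validate inputs", {
  expect_error(ar_priors(sigma_bh_shape = -1), "> 0")
  expect_error(mcmc_config(n_chains = 0), "positive")
  expect_s3_class(ar_priors(), "ar_priors")
})

test_that("daily_summary computes per-fly mean and s.d. of daily bias", {
  panel <- data.frame(
    fly_id = c("a", "a", "a", "b", "b", "c"),
    day = c(1, 2, 3, 1, 2, 1),
    n_right = NA_integer_, n_turns = NA_integer_,
    r_obs = c(0.5, 0.5, 0.5, 0.4, 0.6, 0.9),
    group = "g")
  expect_message(out <- daily_summary(panel), "1 fly")
  expect_equal(nrow(out), 2)
  a <- out[out$fly_id == "a", ]
  expect_equal(a$mean_r, 0.5)
  expect_equal(a$sd_r, 0)
  b <- out[out$fly_id == "b", ]
  expect_equal(b$mean_r, 0.5)
  expect_equal(b$sd_r, sqrt(0.02), tolerance = 1e-10) # sd(c(.4,.6)) ~ 0.1414
})

test_that("driftless, high-count panels yield near-zero daily s.d.", {
  gt <- ground_truth(0.1, 0, 1, turns_per_day = 100000L, seed = 31)
  panel <- gen_daily_bias(gt, 30, 6)
  out <- daily_summary(panel)
  expect_lt(max(out$sd_r), 0.005)
})

test_that("successive-day correlations track the AR(1) persistence", {
  # duplicated day: r = 1
  p0 <- data.frame(fly_id = rep(letters[1:5], 2), day = rep(1:2, each = 5),
                   n_right = NA, n_turns = NA,
                   r_obs = rep(c(0.3, 0.4, 0.5, 0.6, 0.7), 2), group = "g")
  expect_equal(successive_day_correlation(p0)$r, 1)
  # shuffled next day: null correlation across seeds
  rs <- vapply(1:30, function(s) {
    set.seed(s)
    p <- p0
    p$r_obs <- c(rnorm(5), rnorm(5))
    successive_day_correlation(p)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(30))
  # stationary AR(1) truth, near-noiseless observation: r ~ phi
  s_st <- 0.05 / sqrt(1 - 0.8^2)
  gt <- ground_truth(s_st, 0.05, 0.8, turns_per_day = 100000L, seed = 33)
  panel <- gen_daily_bias(gt, 2000, 4)
  rr <- successive_day_correlation(panel)
  expect_equal(mean(rr$r), 0.8, tolerance = 0.03)
  # pairs with too few flies are skipped with a notice
  p2 <- p0[c(1, 2, 6, 7), ]
  expect_message(out2 <- successive_day_correlation(p2), "skipping")
  expect_equal(nrow(out2), 0)
})

test_that("q-values behave at the corners and match the Gaussian overlap", {
  x <- rnorm(2000)
  expect_equal(as.numeric(q_from_draws(x, x)), 0.5)
  qs <- q_from_draws(c(1, 2), c(10, 20))
  expect_lt(as.numeric(qs), attr(qs, "resolution"))
  expect_true(attr(qs, "censored"))
  set.seed(41)
  a <- rnorm(4000); b <- rnorm(4000, 1)
  q <- q_from_draws(a, b)
  # truth: P(a > b) = Phi(-1/sqrt(2)) ~ 0.2398; 3 x MC error ~ 0.03
  expect_lt(abs(as.numeric(q) - pnorm(-1 / sqrt(2))), 0.03)
  # symmetry in group order
  expect_equal(as.numeric(q_from_draws(b, a)), as.numeric(q))
  expect_error(compare_groups(structure(list(groups = "g"), class = "ar_posterior"),
                              "nope", "g", "g"), "unknown parameter")
})

test_that("Gibbs posterior matches an independent quadrature oracle", {
  gt <- ground_truth(0.12, 0.06, 0.6, turns_per_day = 1000L, seed = 21)
  panel <- gen_daily_bias(gt, 40, 6, observation = "direct")
  fit <- fit_ar(panel, cfg = mcmc_config(4, 500, 1000, seed = 2),
                observation = "direct")
  lat <- matrix(panel$r_obs - 0.5, nrow = 40, byrow = TRUE)
  oracle <- ar_quadrature_means(lat)
  got <- setNames(fit$summary$mean, fit$summary$parameter)
  expect_equal(got[["sigma_bh"]], oracle[["sigma_bh"]], tolerance = 0.02)
  expect_equal(got[["sigma_drift"]], oracle[["sigma_drift"]], tolerance = 0.02)
  expect_equal(got[["phi"]], oracle[["phi"]], tolerance = 0.05)
  expect_true(fit$converged)
})

test_that("fit handles missing days and flags convergence diagnostics", {
  gt <- ground_truth(0.10, 0.05, 0.8, turns_per_day = 500L,
                     missing_prob = 0.3, seed = 51)
  panel <- gen_daily_bias(gt, 80, 9)
  fit <- suppressWarnings(fit_ar(panel, cfg = mcmc_config(2, 300, 300, seed = 3)))
  expect_true(all(c("rhat", "ess") %in% names(fit$summary)))
  s <- fit$summary
  # truth within 15% despite 30% missing fly-days
  expect_equal(s$mean[s$parameter == "sigma_bh"], 0.10, tolerance = 0.15)
  expect_equal(s$mean[s$parameter == "sigma_drift"], 0.05, tolerance = 0.15)
  # latent trajectories: one posterior-mean per fly-day
  expect_equal(dim(fit$latent[["group1"]]), c(80, 9))
})

test_that("zero-drift truth concentrates sigma_drift near the boundary", {
  gt <- ground_truth(0.10, 0, 1, turns_per_day = 5000L, seed = 61)
  panel <- gen_daily_bias(gt, 100, 8)
  fit <- suppressWarnings(
    fit_ar(panel, cfg = mcmc_config(2, 400, 400, seed = 4)))
  med <- median(fit$draws[["group1"]]$sigma_drift)
  expect_lt(med, 0.02)
})

test_that("duplicated groups are statistically indistinguishable", {
  gt <- recovery_gt(71)
  panel <- gen_daily_bias(gt, 60, 8)
  dup <- panel
  dup$group <- "copy"
  both <- rbind(panel, dup)
  fit <- suppressWarnings(fit_ar(both, cfg = mcmc_config(2, 300, 400, seed = 5)))
  for (p in c("sigma_bh", "sigma_drift", "phi")) {
    q <- compare_groups(fit, p, "group1", "copy")
    expect_gt(as.numeric(q), 0.35)
  }
})

test_that("inference is invariant to fly relabeling", {
  gt <- recovery_gt(81)
  panel <- gen_daily_bias(gt, 40, 7)
  relab <- panel
  ids <- unique(panel$fly_id)
  relab$fly_id <- setNames(rev(ids), ids)[panel$fly_id]
  relab <- relab[order(relab$fly_id, relab$day), ]
  f1 <- suppressWarnings(fit_ar(panel, cfg = mcmc_config(2, 200, 300, seed = 6)))
  f2 <- suppressWarnings(fit_ar(relab, cfg = mcmc_config(2, 200, 300, seed = 6)))
  # invariant in distribution: posterior means agree to Monte-Carlo error
  expect_equal(f1$summary$mean, f2$summary$mean, tolerance = 0.05)
})

test_that("with almost no dynamics information phi reverts to its prior", {
  gt <- ground_truth(0.1, 0.05, 0.8, turns_per_day = 500L, seed = 91)
  panel <- gen_daily_bias(gt, 50, 2)
  # drop day 2 for every fly but one: a single transition in the whole panel
  keep1 <- unique(panel$fly_id)[1]
  panel <- panel[panel$day == 1 | panel$fly_id == keep1, , drop = FALSE]
  fit <- suppressWarnings(
    fit_ar(panel, cfg = mcmc_config(2, 300, 500, seed = 7)))
  ph <- fit$draws[["group1"]]$phi
  # prior sd is sqrt(10) ~ 3.16; data carry almost no dynamics information
  expect_gt(sd(ph), 1.5)
})

test_that("simulation-based coverage: 90% intervals are roughly calibrated", {
  # simulate directly from the sampler's assumed model (no clipping) and
  # check credible-interval coverage across replicates
  n_rep <- 10
  hits <- matrix(FALSE, n_rep, 3,
                 dimnames = list(NULL, c("sigma_bh", "sigma_drift", "phi")))
  for (r in seq_len(n_rep)) {
    set.seed(500 + r)
    sb <- 0.08 + runif(1, 0, 0.06)
    sd_ <- 0.03 + runif(1, 0, 0.04)
    ph <- runif(1, 0.5, 0.95)
    N <- 60; T <- 7
    x <- matrix(0, N, T)
    x[, 1] <- rnorm(N, 0, sb)
    for (t in 2:T) x[, t] <- ph * x[, t - 1] + rnorm(N, 0, sd_)
    panel <- data.frame(
      fly_id = rep(sprintf("f%03d", 1:N), each = T),
      day = rep(1:T, N), n_right = NA, n_turns = NA,
      r_obs = as.numeric(t(x)) + 0.5, group = "g")
    fit <- suppressWarnings(
      fit_ar(panel, cfg = mcmc_config(2, 250, 350, seed = 600 + r),
             observation = "direct"))
    truth <- c(sigma_bh = sb, sigma_drift = sd_, phi = ph)
    for (p in names(truth)) {
      d <- fit$draws[["g"]][[p]]
      ci <- quantile(d, c(0.05, 0.95))
      hits[r, p] <- ci[1] <= truth[p] && truth[p] <= ci[2]
    }
  }
  expect_gte(colSums(hits)[["sigma_bh"]], 7)
  expect_gte(colSums(hits)[["sigma_drift"]], 7)
  expect_gte(colSums(hits)[["phi"]], 7)
})
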