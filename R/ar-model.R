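#' Priors for the hierarchical AR(1) bias model
#'
#' Defaults are the weakly informative priors of the daily turn-bias model:
#' Inverse-Gamma(3, 1) on both scale parameters (on the scale itself, not the
#' variance) and Normal(0, 10) (variance 10) on the persistence `phi`, with a
#' diffuse Normal(0, 10) prior associated with missing observations.
#'
#' @param sigma_bh_shape,sigma_bh_scale Inverse-Gamma shape/scale for the
#'   initial-spread parameter `sigma_bh`.
#' @param sigma_drift_shape,sigma_drift_scale Inverse-Gamma shape/scale for
#'   the daily innovation scale `sigma_drift`.
#' @param phi_mean,phi_var Normal prior on `phi` (no truncation).
#' @param missing_mean,missing_var Prior on a missing day's observation; in
#'   the marginalized sampler missing days contribute no measurement update,
#'   so this prior is recorded for completeness.
#' @return An object of class `"ar_priors"`.
#' @export
ar_priors <- function(sigma_bh_shape = 3, sigma_bh_scale = 1,
                      sigma_drift_shape = 3, sigma_drift_scale = 1,
                      phi_mean = 0, phi_var = 10,
                      missing_mean = 0, missing_var = 10) {
  vals <- c(sigma_bh_shape, sigma_bh_scale, sigma_drift_shape,
            sigma_drift_scale, phi_var, missing_var)
  if (any(vals <= 0)) stop("prior shapes, scales and variances must be > 0")
  structure(list(sigma_bh_shape = sigma_bh_shape,
                 sigma_bh_scale = sigma_bh_scale,
                 sigma_drift_shape = sigma_drift_shape,
                 sigma_drift_scale = sigma_drift_scale,
                 phi_mean = phi_mean, phi_var = phi_var,
                 missing_mean = missing_mean, missing_var = missing_var),
            class = "ar_priors")
}

#' MCMC configuration
#'
#' @param n_chains Number of chains (default 4).
#' @param n_warmup Discarded draws per chain (default 1000).
#' @param n_draws Retained draws per chain (default 2000).
#' @param seed Integer seed; chains use derived substreams.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 4L, n_warmup = 1000L, n_draws = 2000L,
                        seed = 1L) {
  v <- c(n_chains, n_warmup, n_draws)
  if (any(v < 1) || any(v != round(v))) stop("MCMC settings must be positive integers")
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "mcmc_config")
}

# univariate slice sampler (stepping out + shrinkage), Neal 2003
.slice <- function(x0, logf, unif, w = 0.3, max_steps = 100L) {
  f0 <- logf(x0)
  z <- f0 + log(unif(1L))
  l <- x0 - w * unif(1L); r <- l + w
  j <- floor(max_steps * unif(1L)); k <- max_steps - 1L - j
  while (j > 0L && logf(l) > z) { l <- l - w; j <- j - 1L }
  while (k > 0L && logf(r) > z) { r <- r + w; k <- k - 1L }
  repeat {
    x1 <- l + unif(1L) * (r - l)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# One-group Gibbs sampler. y, v: N x T matrices (NA in y = missing).
# Returns draws (matrix iter x 3) and accumulated latent means.
.gibbs_ar <- function(y, v, priors, n_warmup, n_draws, seed, init_scale = 1) {
  N <- nrow(y); T <- ncol(y)
  obs <- is.finite(y)
  rs <- .rng_local(as.integer(seed))
  # overdispersed but sane starting values
  sb <- 0.1 * init_scale
  sd_ <- 0.05 * init_scale
  ph <- min(0.95, 0.5 * init_scale)
  x <- ifelse(obs, y, 0)
  n_iter <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, 3L,
                  dimnames = list(NULL, c("sigma_bh", "sigma_drift", "phi")))
  x_acc <- matrix(0, N, T)
  a_b <- priors$sigma_bh_shape; b_b <- priors$sigma_bh_scale
  a_d <- priors$sigma_drift_shape; b_d <- priors$sigma_drift_scale
  phi_prec0 <- 1 / priors$phi_var
  phi_m0 <- priors$phi_mean

  for (it in seq_len(n_iter)) {
    ## --- FFBS draw of latent trajectories, vectorized over flies ---
    m <- matrix(0, N, T); P <- matrix(0, N, T)
    mp <- rep(0, N); Pp <- rep(sb^2, N)
    for (t in seq_len(T)) {
      if (t > 1L) { mp <- ph * m[, t - 1L]; Pp <- ph^2 * P[, t - 1L] + sd_^2 }
      o <- obs[, t]
      m[, t] <- mp; P[, t] <- Pp
      if (any(o)) {
        K <- Pp[o] / (Pp[o] + v[, t][o])
        m[o, t] <- mp[o] + K * (y[, t][o] - mp[o])
        P[o, t] <- (1 - K) * Pp[o]
      }
    }
    x[, T] <- m[, T] + sqrt(pmax(P[, T], 0)) * rs$norm(N)
    if (T > 1L) for (t in (T - 1L):1L) {
      den <- ph^2 * P[, t] + sd_^2
      h <- ifelse(den > 0, ph * P[, t] / den, 0)
      cm <- m[, t] + h * (x[, t + 1L] - ph * m[, t])
      cv <- pmax(P[, t] * ifelse(den > 0, sd_^2 / den, 0), 0)
      x[, t] <- cm + sqrt(cv) * rs$norm(N)
    }

    ## --- phi | x, sigma_drift (conjugate Normal) ---
    if (T > 1L) {
      xl <- x[, -T, drop = FALSE]; xn <- x[, -1L, drop = FALSE]
      prec <- phi_prec0 + sum(xl^2) / sd_^2
      mu_ph <- (phi_prec0 * phi_m0 + sum(xl * xn) / sd_^2) / prec
      ph <- mu_ph + rs$norm(1L) / sqrt(prec)
      ssd <- sum((xn - ph * xl)^2)
      Md <- N * (T - 1L)
    } else { ssd <- 0; Md <- 0L }

    ## --- scales | x (slice sampling on log sigma) ---
    ss1 <- sum(x[, 1L]^2)
    lf_b <- function(u) {
      s <- exp(u)
      -(a_b + 1) * u - b_b / s - N * u - ss1 / (2 * s^2) + u
    }
    sb <- exp(.slice(log(sb), lf_b, rs$unif))
    if (Md > 0L) {
      lf_d <- function(u) {
        s <- exp(u)
        -(a_d + 1) * u - b_d / s - Md * u - ssd / (2 * s^2) + u
      }
      sd_ <- exp(.slice(log(sd_), lf_d, rs$unif))
    } else {
      # no transitions: sample sigma_drift from its prior
      sd_ <- 1 / stats::qgamma(rs$unif(1L), shape = a_d, rate = b_d)
    }

    if (it > n_warmup) {
      draws[it - n_warmup, ] <- c(sb, sd_, ph)
      x_acc <- x_acc + x
    }
  }
  list(draws = draws, x_mean = x_acc / n_draws)
}

#' Fit the hierarchical AR(1) model of daily turn bias
#'
#' Per group, flies' mean-centered biases follow
#' `x[i, 1] ~ Normal(0, sigma_bh^2)`,
#' `x[i, t] = phi * x[i, t-1] + Normal(0, sigma_drift^2)`, and an observed
#' right fraction contributes `R[i, t] - 0.5 = x[i, t] + e[i, t]` with
#' known binomial sampling variance (counts mode) or exactly (direct mode).
#' Missing days remain latent states with no measurement update. Sampling is
#' by a blocked Gibbs sampler: forward-filter backward-sample for the latent
#' trajectories, a conjugate Normal update for `phi`, and slice sampling for
#' the two scales (whose Inverse-Gamma priors act on the scale, not the
#' variance). Convergence is gated at split-Rhat <= 1.05 and ESS >= 400 per
#' reported parameter; failures are flagged, never silent.
#'
#' @param panel A `behavioral_panel` data frame (columns `fly_id`, `day`,
#'   `n_right`, `n_turns`, `r_obs`, `group`).
#' @param priors An [ar_priors()] object.
#' @param cfg An [mcmc_config()] object.
#' @param observation `"counts"`: Gaussian measurement error with moment-
#'   matched binomial variance `p(1-p)/n_turns`; `"direct"`: the centered
#'   fraction is treated as the latent bias up to negligible error.
#' @return Object of class `"ar_posterior"`: list with `draws` (per group, a
#'   data frame `chain`, `iter`, `sigma_bh`, `sigma_drift`, `phi`), `latent`
#'   (per group, posterior-mean trajectories, flies x days), `summary`
#'   (per group/parameter mean, 2.5%, 97.5%, Rhat, ESS), `converged` flag,
#'   `groups`, `cfg`, `priors`.
#' @export
fit_ar <- function(panel, priors = ar_priors(), cfg = mcmc_config(),
                   observation = c("counts", "direct")) {
  observation <- match.arg(observation)
  if (!all(c("fly_id", "day", "r_obs", "group") %in% names(panel)))
    stop("panel must have columns fly_id, day, r_obs, group")
  groups <- unique(panel$group)
  draws <- list(); latent <- list(); summ <- list()
  for (g in groups) {
    pg <- panel[panel$group == g, , drop = FALSE]
    if (nrow(pg) == 0L) stop("empty group: ", g)
    flies <- unique(pg$fly_id)
    days <- seq(min(pg$day), max(pg$day))
    if (max(table(pg$fly_id)) < 2L)
      stop("group ", g, " has no fly with >= 2 observed days")
    N <- length(flies); T <- length(days)
    y <- matrix(NA_real_, N, T, dimnames = list(flies, days))
    v <- matrix(1, N, T)
    ii <- match(pg$fly_id, flies); tt <- match(pg$day, days)
    y[cbind(ii, tt)] <- pg$r_obs - 0.5
    if (observation == "counts" && all(is.finite(pg$n_turns)) &&
        all(is.finite(pg$n_right))) {
      # binomial variance from each fly's mean fraction: a per-day plug-in
      # p_hat(1-p_hat)/n is anti-correlated with the realized sampling error
      # (noisy days look spuriously precise) and inflates inferred dynamics
      tot_r <- tapply(pg$n_right, pg$fly_id, sum)[flies]
      tot_n <- tapply(pg$n_turns, pg$fly_id, sum)[flies]
      p_fly <- ((tot_r + 0.5) / (tot_n + 1))[match(pg$fly_id, flies)]
      v[cbind(ii, tt)] <- pmax(p_fly * (1 - p_fly) / pg$n_turns, 1e-8)
    } else {
      v[cbind(ii, tt)] <- 1e-10
    }
    ch_draws <- vector("list", cfg$n_chains)
    x_mean <- matrix(0, N, T)
    for (c in seq_len(cfg$n_chains)) {
      res <- .gibbs_ar(y, v, priors, cfg$n_warmup, cfg$n_draws,
                       seed = cfg$seed * 131L + c +
                         1000L * match(g, groups),
                       init_scale = c(1, 2, 0.5, 1.5)[(c - 1L) %% 4L + 1L])
      ch_draws[[c]] <- res$draws
      x_mean <- x_mean + res$x_mean / cfg$n_chains
    }
    dd <- do.call(rbind, lapply(seq_along(ch_draws), function(c)
      data.frame(chain = c, iter = seq_len(cfg$n_draws), ch_draws[[c]])))
    draws[[g]] <- dd
    latent[[g]] <- x_mean
    ml <- coda::mcmc.list(lapply(ch_draws, coda::mcmc))
    rhat <- coda::gelman.diag(ml, autoburnin = FALSE,
                              multivariate = FALSE)$psrf[, 1L]
    ess <- coda::effectiveSize(ml)
    for (p in c("sigma_bh", "sigma_drift", "phi")) {
      q <- stats::quantile(dd[[p]], c(0.025, 0.975), names = FALSE)
      summ[[length(summ) + 1L]] <- data.frame(
        group = g, parameter = p, mean = mean(dd[[p]]),
        q2.5 = q[1L], q97.5 = q[2L], rhat = unname(rhat[p]),
        ess = unname(ess[p]))
    }
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  converged <- all(summary$rhat <= 1.05, na.rm = TRUE) &&
    all(summary$ess >= 400, na.rm = TRUE)
  if (!converged)
    warning("convergence gate failed (Rhat > 1.05 or ESS < 400); ",
            "inspect $summary", call. = FALSE)
  structure(list(draws = draws, latent = latent, summary = summary,
                 converged = converged, groups = groups, cfg = cfg,
                 priors = priors, observation = observation),
            class = "ar_posterior")
}

#' @export
print.ar_posterior <- function(x, ...) {
  cat("Hierarchical AR(1) posterior (", length(x$groups), " group(s), ",
      x$cfg$n_chains, " chains x ", x$cfg$n_draws, " draws)\n", sep = "")
  print(x$summary, digits = 4)
  if (!x$converged) cat("WARNING: convergence gate failed\n")
  invisible(x)
}

#' Posterior q-value for a between-group parameter difference
#'
#' The q-value is the minimum posterior probability that the difference
#' between the two groups' parameters is less than or equal to zero,
#' evaluated over all pairs of MCMC draws (ties counted one half, so two
#' identical draw sets give exactly 0.5). Fully separated draw sets are
#' reported as bounded below the draw resolution.
#'
#' @param post An `ar_posterior` object.
#' @param parameter One of `"sigma_bh"`, `"sigma_drift"`, `"phi"`.
#' @param group_a,group_b Group labels present in the posterior.
#' @return A numeric scalar of class `"q_value"` in `[0, 0.5]` with
#'   attributes `resolution` (`1 / total draws`) and `censored` (`TRUE` when
#'   the sets do not overlap, i.e. the value should be read as
#'   `q < resolution`).
#' @export
compare_groups <- function(post, parameter, group_a, group_b) {
  if (!parameter %in% c("sigma_bh", "sigma_drift", "phi"))
    stop("unknown parameter: ", parameter)
  for (g in c(group_a, group_b))
    if (!g %in% post$groups) stop("group not in posterior: ", g)
  a <- post$draws[[group_a]][[parameter]]
  b <- post$draws[[group_b]][[parameter]]
  q_from_draws(a, b)
}

#' @rdname compare_groups
#' @param a,b Numeric vectors of posterior draws (used directly instead of an
#'   `ar_posterior` object).
#' @export
q_from_draws <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  # pairs with a > b (+ half-ties) via the rank-sum statistic
  n_gt <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  p_gt <- n_gt / (na * nb)
  q <- min(p_gt, 1 - p_gt)
  res <- 1 / (na + nb)
  structure(q, resolution = res, censored = q == 0, class = "q_value")
}

#' @export
print.q_value <- function(x, ...) {
  if (isTRUE(attr(x, "censored")))
    cat(sprintf("q < %.3g (no overlapping draws)\n", attr(x, "resolution")))
  else cat(sprintf("q = %.4g\n", as.numeric(x)))
  invisible(x)
}

#' Per-fly summary of daily right bias
#'
#' One record per fly: mean and standard deviation of the observed daily
#' right fractions (missing days excluded). Flies with fewer than two
#' observed days are dropped with a notice.
#'
#' @param panel A `behavioral_panel` data frame.
#' @return Data frame with columns `fly_id`, `group`, `mean_r`, `sd_r`,
#'   `n_days`.
#' @export
daily_summary <- function(panel) {
  sp <- split(panel, panel$fly_id)
  drop <- names(sp)[vapply(sp, nrow, 0L) < 2L]
  if (length(drop))
    message("dropping ", length(drop), " fly(ies) with < 2 observed days")
  sp <- sp[vapply(sp, nrow, 0L) >= 2L]
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    fly_id = d$fly_id[1L], group = d$group[1L],
    mean_r = mean(d$r_obs), sd_r = stats::sd(d$r_obs), n_days = nrow(d))))
  rownames(out) <- NULL
  out
}

#' Correlation of fly handedness between successive assay days
#'
#' For each consecutive pair of observed assay days, the Pearson correlation
#' across flies of daily right fractions. Pairs with fewer than 3 flies
#' observed on both days are skipped with a notice.
#'
#' @param panel A `behavioral_panel` data frame.
#' @return Data frame with columns `day_a`, `day_b`, `r`, `n`.
#' @export
successive_day_correlation <- function(panel) {
  days <- sort(unique(panel$day))
  out <- list()
  for (k in seq_len(length(days) - 1L)) {
    da <- panel[panel$day == days[k], c("fly_id", "r_obs")]
    db <- panel[panel$day == days[k + 1L], c("fly_id", "r_obs")]
    m <- merge(da, db, by = "fly_id")
    if (nrow(m) < 3L) {
      message("skipping day pair ", days[k], "-", days[k + 1L],
              ": only ", nrow(m), " flies observed on both")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      day_a = days[k], day_b = days[k + 1L],
      r = stats::cor(m$r_obs.x, m$r_obs.y), n = nrow(m))
  }
  if (!length(out)) return(data.frame(day_a = integer(), day_b = integer(),
                                      r = numeric(), n = integer()))
  do.call(rbind, out)
}
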