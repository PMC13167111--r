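#' Parameters of the age-structured preference-drift population model
#'
#' The population is a deterministic density `n[phi, age]` over 200
#' preference bins on `[-1, 1]` and integer ages up to a maximum lifespan of
#' `10 + 2 * a_min` days. Each day preferences diffuse (s.d. `sigma_d`),
#' individuals survive in proportion to a Gaussian of their distance from the
#' day's environmental optimum (width `sigma_e`) times a bounding envelope
#' about the long-term mean (width `sigma_max`), everyone ages, and mature
#' individuals produce `beta` offspring whose preferences are normally
#' distributed about the long-term environmental mean with s.d. `sigma_b`.
#'
#' @param sigma_d Daily drift s.d. (preference units/day).
#' @param sigma_b Newborn preference s.d. (bet-hedging spread).
#' @param sigma_e Survival kernel s.d. (default 0.125).
#' @param sigma_max Bounding envelope s.d. (default 3).
#' @param a_min Age of reproductive maturity, days (default 10).
#' @param beta Offspring per mature individual per day (default 40).
#' @param n_bins Number of preference bins (default 200).
#' @param domain Preference domain (default `c(-1, 1)`).
#' @param max_age Maximum age in days (default `10 + 2 * a_min`).
#' @param mu_env Long-term environmental mean (default 0).
#' @param bounding `"envelope"`: daily multiplicative Gaussian envelope;
#'   `"ou"`: fold the reversion into the drift kernel instead
#'   (mean-reverting diffusion with stationary s.d. `sigma_max`, no
#'   envelope factor).
#' @return Object of class `"popsim_params"` with precomputed bin midpoints.
#' @export
popsim_params <- function(sigma_d = 0, sigma_b = 0, sigma_e = 0.125,
                          sigma_max = 3, a_min = 10L, beta = 40,
                          n_bins = 200L, domain = c(-1, 1),
                          max_age = 10L + 2L * a_min, mu_env = 0,
                          bounding = c("envelope", "ou")) {
  bounding <- match.arg(bounding)
  if (any(c(sigma_d, sigma_b, sigma_e, sigma_max) < 0))
    stop("all sigma parameters must be >= 0")
  if (a_min < 1L) stop("'a_min' must be >= 1")
  if (beta < 0) stop("'beta' must be >= 0")
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  h <- diff(domain) / n_bins
  structure(list(sigma_d = sigma_d, sigma_b = sigma_b, sigma_e = sigma_e,
                 sigma_max = sigma_max, a_min = as.integer(a_min),
                 beta = beta, n_bins = as.integer(n_bins), domain = domain,
                 max_age = as.integer(max_age), mu_env = mu_env,
                 bounding = bounding, h = h,
                 mids = seq(domain[1L] + h / 2, domain[2L] - h / 2,
                            length.out = n_bins)),
            class = "popsim_params")
}

# Discretized (truncated, renormalized) Gaussian over the preference bins.
.bin_gaussian <- function(params, mean, sd) {
  if (sd == 0) {
    out <- numeric(params$n_bins)
    i <- findInterval(mean, seq(params$domain[1L], params$domain[2L],
                                length.out = params$n_bins + 1L),
                      all.inside = TRUE)
    out[i] <- 1
    return(out)
  }
  edges <- seq(params$domain[1L], params$domain[2L],
               length.out = params$n_bins + 1L)
  p <- diff(stats::pnorm(edges, mean, sd))
  p / sum(p)
}

# Column-normalized Gaussian drift kernel K[i, j] = P(move to bin i | bin j);
# per-column renormalization at the boundaries conserves mass exactly.
.drift_kernel <- function(params, centers = params$mids) {
  if (params$sigma_d == 0 && identical(centers, params$mids))
    return(diag(params$n_bins))
  sdv <- params$sigma_d
  K <- matrix(0, params$n_bins, params$n_bins)
  for (j in seq_len(params$n_bins))
    K[, j] <- .bin_gaussian(params, centers[j], sdv)
  K
}

# Effective daily kernel for the "ou" bounding mode: kernel means shrink
# toward mu_env so the drift process is stationary with s.d. sigma_max.
.ou_kernel <- function(params) {
  lambda <- if (params$sigma_d >= params$sigma_max) 0 else
    sqrt(1 - (params$sigma_d / params$sigma_max)^2)
  centers <- params$mu_env + lambda * (params$mids - params$mu_env)
  sdv <- params$sigma_d
  K <- matrix(0, params$n_bins, params$n_bins)
  for (j in seq_len(params$n_bins))
    K[, j] <- .bin_gaussian(params, centers[j], sdv)
  K
}

#' Initialize a population state
#'
#' An age-0 cohort of total mass `n0`, with preferences drawn from a
#' truncated-renormalized `Normal(initial_mean, sigma_b^2)` discretized onto
#' the bins (`sigma_b = 0` puts all mass in the bin containing the mean).
#'
#' @param params A [popsim_params()] object.
#' @param initial_mean Center of the initial preference distribution.
#' @param n0 Initial total mass (> 0).
#' @return Object of class `"population_state"`: list with `n` (bins x ages
#'   matrix, normalized to total 1), `log_total` (log of the true total
#'   mass), `params`.
#' @export
init_population <- function(params, initial_mean = 0, n0 = 1) {
  if (n0 <= 0) stop("'n0' must be > 0")
  if (initial_mean < params$domain[1L] || initial_mean > params$domain[2L])
    stop("'initial_mean' outside the preference domain")
  n <- matrix(0, params$n_bins, params$max_age + 1L)
  n[, 1L] <- .bin_gaussian(params, initial_mean, params$sigma_b)
  structure(list(n = n, log_total = log(n0), params = params),
            class = "population_state")
}

#' Advance the population by one day
#'
#' Daily update order: (1) drift — each age class's preference distribution
#' is convolved with the mass-conserving Gaussian kernel; (2) survival —
#' multiplication by `exp(-(phi - E_t)^2 / (2 sigma_e^2))`; (3) bounding —
#' multiplication by `exp(-(phi - mu_env)^2 / (2 sigma_max^2))` (skipped in
#' `"ou"` mode, where reversion lives in the kernel); (4) aging — all ages
#' increment, individuals beyond the maximum lifespan are removed;
#' (5) births — an age-0 cohort of mass `beta` times the mature mass,
#' spread as the newborn distribution. Total mass is tracked in log space.
#'
#' @param state A `population_state`.
#' @param E_t The day's environmental optimum (finite).
#' @param kernel Optional precomputed drift kernel (recomputed otherwise).
#' @return The updated `population_state`.
#' @export
step_population <- function(state, E_t, kernel = NULL) {
  params <- state$params
  if (!is.finite(E_t)) stop("'E_t' must be finite")
  if (is.null(kernel))
    kernel <- if (params$bounding == "ou") .ou_kernel(params)
              else .drift_kernel(params)
  n <- kernel %*% state$n
  surv <- exp(-(params$mids - E_t)^2 / (2 * params$sigma_e^2))
  if (params$bounding == "envelope" && is.finite(params$sigma_max))
    surv <- surv * exp(-(params$mids - params$mu_env)^2 /
                         (2 * params$sigma_max^2))
  n <- n * surv
  # aging: shift columns right, drop the oldest
  n <- cbind(0, n[, -ncol(n), drop = FALSE])
  mature <- sum(n[, (params$a_min + 1L):ncol(n), drop = FALSE])
  if (params$beta > 0 && mature > 0)
    n[, 1L] <- params$beta * mature * .bin_gaussian(params, params$mu_env,
                                                    params$sigma_b)
  tot <- sum(n)
  if (!is.finite(tot)) stop("non-finite abundances during step")
  if (tot <= 0)
    return(structure(list(n = n * 0, log_total = -Inf, params = params),
                     class = "population_state"))
  structure(list(n = n / tot, log_total = state$log_total + log(tot),
                 params = params), class = "population_state")
}

#' Run the population model over an environment series
#'
#' Iterates [step_population()] over the days of `env`, tracking the total
#' population in log space (per-day renormalization avoids overflow and
#' underflow). The run is fully deterministic given its inputs.
#'
#' @param env An `environment_series` data frame (columns `day`, `value`) or
#'   a numeric vector of daily optima.
#' @param params A [popsim_params()] object.
#' @param n0 Initial total mass.
#' @param initial_mean Center of the initial preference distribution.
#' @param n_days Number of days to run (default: length of `env`).
#' @return Object of class `"growth_result"`: list with `log_pop` (per-day
#'   log total population, length `n_days`), `final_log_fold_change`,
#'   `extinct` flag, `state` (final `population_state`).
#' @export
run_popsim <- function(env, params, n0 = 1, initial_mean = params$mu_env,
                       n_days = NULL) {
  E <- if (is.data.frame(env)) env$value else as.numeric(env)
  if (is.null(n_days)) n_days <- length(E)
  if (length(E) < n_days) stop("environment does not cover the run length")
  state <- init_population(params, initial_mean, n0)
  kernel <- if (params$bounding == "ou") .ou_kernel(params)
            else .drift_kernel(params)
  log0 <- state$log_total
  log_pop <- numeric(n_days)
  extinct <- FALSE
  for (t in seq_len(n_days)) {
    state <- tryCatch(step_population(state, E[t], kernel),
                      error = function(e)
                        stop("day ", t, ": ", conditionMessage(e)))
    log_pop[t] <- state$log_total
    if (!is.finite(state$log_total)) {
      extinct <- TRUE
      log_pop[t:n_days] <- -Inf
      break
    }
  }
  structure(list(log_pop = log_pop,
                 final_log_fold_change = log_pop[n_days] - log0,
                 extinct = extinct, state = state),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat("Population run over", length(x$log_pop), "days:",
      if (x$extinct) "EXTINCT" else
        sprintf("log fold change %.4f", x$final_log_fold_change), "\n")
  invisible(x)
}

#' Leslie-matrix oracle for degenerate (preference-free) runs
#'
#' When the preference distribution is a fixed delta (no drift, no
#' bet-hedging) in a constant environment, the population model collapses to
#' a scalar age-structured process: survival `s` per day on the
#' subdiagonal, fecundity `s * beta` for individuals reaching mature ages.
#' Its asymptotic log growth rate is the log of the dominant eigenvalue,
#' computed either by direct eigendecomposition or by power iteration.
#'
#' @param params A [popsim_params()] object (uses `a_min`, `beta`,
#'   `max_age`).
#' @param survival_per_day Scalar daily survival in `(0, 1]`.
#' @param method `"eigen"` or `"power"`.
#' @return Asymptotic per-day log growth rate.
#' @export
leslie_oracle <- function(params, survival_per_day,
                          method = c("eigen", "power")) {
  method <- match.arg(method)
  if (survival_per_day <= 0 || survival_per_day > 1)
    stop("'survival_per_day' must lie in (0, 1]")
  L <- leslie_matrix(params, survival_per_day)
  if (method == "eigen") {
    lam <- max(Re(eigen(L, only.values = TRUE)$values))
  } else {
    x <- rep(1, nrow(L)); lam <- 1
    for (k in seq_len(20000L)) {
      y <- L %*% x
      lam_new <- sum(y)
      y <- y / lam_new
      if (max(abs(y - x)) < 1e-14) { x <- y; lam <- lam_new; break }
      x <- y; lam <- lam_new
    }
  }
  log(lam)
}

#' @rdname leslie_oracle
#' @export
leslie_matrix <- function(params, survival_per_day) {
  a_max <- params$max_age
  L <- matrix(0, a_max + 1L, a_max + 1L)
  for (a in 0:(a_max - 1L)) {
    L[a + 2L, a + 1L] <- survival_per_day
    if (a + 1L >= params$a_min)
      L[1L, a + 1L] <- L[1L, a + 1L] + survival_per_day * params$beta
  }
  L
}
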