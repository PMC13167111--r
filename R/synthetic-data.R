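#' Ground-truth parameters for a synthetic behavioral panel
#'
#' Bundles the generative parameters of the daily turn-bias process: an
#' individual's latent right bias starts at `Normal(mu, sigma_bh^2)` and each
#' day moves by an AR(1) step with persistence `phi` and innovation s.d.
#' `sigma_drift`. Observed right fractions are binomial samples of
#' `turns_per_day` turns.
#'
#' @param sigma_bh Non-negative s.d. of the initial (day-1) bias across
#'   individuals, in bias units (deviation of right fraction from 0.5).
#' @param sigma_drift Non-negative s.d. of the daily bias innovation.
#' @param phi AR(1) persistence in `[0, 1]`; 1 is a pure random walk, 0 a
#'   memoryless reversion to the population mean.
#' @param mu Population mean bias (0 means an unbiased population).
#' @param turns_per_day Positive integer number of scored turns per assay day.
#' @param missing_prob Probability in `[0, 1)` that any fly-day is unobserved.
#' @param seed Integer seed; the panel generator fans it out into per-fly
#'   substreams, so fly `i`'s trajectory does not depend on `n_flies`.
#' @return An object of class `"ground_truth"`.
#' @seealso [gen_daily_bias()]
#' @export
ground_truth <- function(sigma_bh, sigma_drift, phi, mu = 0,
                         turns_per_day = 100L, missing_prob = 0,
                         seed = 1L) {
  stopifnot(is.numeric(sigma_bh), length(sigma_bh) == 1L,
            is.numeric(sigma_drift), length(sigma_drift) == 1L,
            is.numeric(phi), length(phi) == 1L)
  if (sigma_bh < 0) stop("'sigma_bh' must be >= 0")
  if (sigma_drift < 0) stop("'sigma_drift' must be >= 0")
  if (phi < 0 || phi > 1) stop("'phi' must lie in [0, 1]")
  if (missing_prob < 0 || missing_prob >= 1)
    stop("'missing_prob' must lie in [0, 1)")
  turns_per_day <- as.integer(turns_per_day)
  if (is.na(turns_per_day) || turns_per_day < 1L)
    stop("'turns_per_day' must be a positive integer")
  structure(list(sigma_bh = sigma_bh, sigma_drift = sigma_drift, phi = phi,
                 mu = mu, turns_per_day = turns_per_day,
                 missing_prob = missing_prob, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth: sigma_bh =", x$sigma_bh,
      " sigma_drift =", x$sigma_drift, " phi =", x$phi, "\n")
  cat("  mu =", x$mu, " turns/day =", x$turns_per_day,
      " missing_prob =", x$missing_prob, " seed =", x$seed, "\n")
  invisible(x)
}

# Deterministic per-fly substream seed: stable under changes of n_flies.
.fly_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a synthetic daily turn-bias panel
#'
#' Simulates latent biases `x[i, 1] ~ Normal(mu, sigma_bh^2)`,
#' `x[i, t] = mu + phi * (x[i, t-1] - mu) + Normal(0, sigma_drift^2)`, then
#' observes each fly-day as a binomial draw of `turns_per_day` turns with
#' right-turn probability `x[i, t] + 0.5` clipped to `[0.01, 0.99]`. Days are
#' dropped independently with probability `missing_prob` (or per a supplied
#' mask). The full latent matrix is retained as an attribute for validation.
#'
#' @param gt A [ground_truth()] object.
#' @param n_flies,n_days Panel dimensions (`n_flies >= 1`, `n_days >= 2`).
#' @param group Group label attached to every row.
#' @param observation `"binomial"` for the counts layer, `"direct"` to record
#'   the latent fraction `x + 0.5` exactly (no sampling noise).
#' @param missing_mask Optional logical vector of length `n_days` (`TRUE` =
#'   day assayed) applied to every fly instead of i.i.d. dropout; see
#'   [assay_day_mask()].
#' @return A data frame of class `"behavioral_panel"` with columns `fly_id`,
#'   `day`, `n_right`, `n_turns`, `r_obs`, `group`; missing fly-days are
#'   absent rows. Attribute `"latent"` holds the `n_flies x n_days` latent
#'   bias matrix; attribute `"ground_truth"` the generator parameters.
#' @examples
#' gt <- ground_truth(sigma_bh = 0.1, sigma_drift = 0.05, phi = 0.8,
#'                    turns_per_day = 500, seed = 7)
#' panel <- gen_daily_bias(gt, n_flies = 20, n_days = 9)
#' head(panel)
#' @export
gen_daily_bias <- function(gt, n_flies, n_days, group = "group1",
                           observation = c("binomial", "direct"),
                           missing_mask = NULL) {
  if (!inherits(gt, "ground_truth")) stop("'gt' must be a ground_truth object")
  observation <- match.arg(observation)
  n_flies <- as.integer(n_flies); n_days <- as.integer(n_days)
  if (n_flies < 1L) stop("'n_flies' must be >= 1")
  if (n_days < 2L) stop("'n_days' must be >= 2")
  if (!is.null(missing_mask) && length(missing_mask) != n_days)
    stop("'missing_mask' must have length n_days")

  latent <- matrix(NA_real_, n_flies, n_days)
  rows <- vector("list", n_flies)
  for (i in seq_len(n_flies)) {
    rs <- .rng_local(.fly_seed(gt$seed, i))
    x <- numeric(n_days)
    x[1L] <- gt$mu + gt$sigma_bh * rs$norm(1L)
    innov <- gt$sigma_drift * rs$norm(n_days - 1L)
    for (t in 2L:n_days)
      x[t] <- gt$mu + gt$phi * (x[t - 1L] - gt$mu) + innov[t - 1L]
    latent[i, ] <- x
    p <- pmin(pmax(x + 0.5, 0.01), 0.99)
    if (observation == "binomial") {
      n_right <- rs$binom(n_days, gt$turns_per_day, p)
      r_obs <- n_right / gt$turns_per_day
    } else {
      n_right <- rep(NA_integer_, n_days)
      r_obs <- p
    }
    keep <- if (is.null(missing_mask)) {
      rs$unif(n_days) >= gt$missing_prob
    } else as.logical(missing_mask)
    rows[[i]] <- data.frame(
      fly_id = sprintf("fly_%04d", i), day = seq_len(n_days),
      n_right = n_right, n_turns = gt$turns_per_day, r_obs = r_obs,
      group = group, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  structure(panel, latent = latent, ground_truth = gt,
            class = c("behavioral_panel", "data.frame"))
}

# Local RNG sandbox: draws do not disturb (or depend on) the global stream.
.rng_local <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  draw <- function(fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fun()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(norm = function(n) draw(function() stats::rnorm(n)),
       unif = function(n) draw(function() stats::runif(n)),
       binom = function(n, size, prob) draw(function() stats::rbinom(n, size, prob)))
}

#' Assay-day missingness mask
#'
#' Preset weekly assay schedule: flies scored on a fixed number of days per
#' week, the remaining days unobserved (the cadence of a thrice-weekly,
#' multi-week handedness assay).
#'
#' @param n_weeks Number of weeks.
#' @param days_per_week Assayed days per 7-day week (first `days_per_week`
#'   days of each week, spread as evenly as 7 days allow).
#' @return Logical vector of length `7 * n_weeks`; `TRUE` = assayed.
#' @export
assay_day_mask <- function(n_weeks = 3L, days_per_week = 3L) {
  stopifnot(days_per_week >= 1L, days_per_week <= 7L)
  on_days <- round(seq(1, 7, length.out = days_per_week + 1L))[seq_len(days_per_week)]
  rep(seq_len(7L) %in% on_days, n_weeks)
}

#' Generate a biased circular-arena random walk
#'
#' Produces a centroid track on an annulus inside a circular arena: the
#' angular coordinate advances by a deterministic bias term plus Gaussian
#' jitter, and the radial coordinate follows a mean-reverting jitter around a
#' mid-annulus radius, clipped inside the wall. A positive `bias` circles
#' counter-clockwise on average.
#'
#' @param bias Signed circling strength in `[-1, 1]`; `|bias| = 1` with
#'   `angular_noise = 0` gives monotone rotation.
#' @param duration_s Track duration in seconds.
#' @param fps Frames per second (> 0).
#' @param seed Integer seed.
#' @param arena_radius Arena radius in mm.
#' @param angular_noise S.d. of the per-frame angular jitter (radians).
#' @param radial_noise S.d. of the per-frame radial jitter (mm).
#' @param max_turn_rate Peak angular speed (rad/s) reached at `|bias| = 1`.
#' @return A data frame of class `"centroid_track"` with columns `time`, `x`,
#'   `y` (mm) and attributes `center` and `radius`.
#' @export
gen_circular_walk <- function(bias, duration_s, fps = 30, seed = 1L,
                              arena_radius = 28, angular_noise = 0.15,
                              radial_noise = 0.5, max_turn_rate = 1.5) {
  if (abs(bias) > 1) stop("'bias' must lie in [-1, 1]")
  if (fps <= 0) stop("'fps' must be > 0")
  n <- max(2L, floor(duration_s * fps) + 1L)
  rs <- .rng_local(as.integer(seed))
  dtheta <- bias * max_turn_rate / fps + angular_noise * rs$norm(n - 1L)
  theta <- cumsum(c(rs$unif(1L) * 2 * pi, dtheta))
  r0 <- 0.7 * arena_radius
  dr <- radial_noise * rs$norm(n - 1L)
  r <- numeric(n); r[1L] <- r0
  for (k in 2L:n) r[k] <- r[k - 1L] + 0.1 * (r0 - r[k - 1L]) + dr[k - 1L]
  r <- pmin(pmax(r, 0), arena_radius * 0.98)
  structure(data.frame(time = (seq_len(n) - 1L) / fps,
                       x = r * cos(theta), y = r * sin(theta)),
            center = c(0, 0), radius = arena_radius,
            class = c("centroid_track", "data.frame"))
}

#' Generate a colored-noise time series with contiguous gaps
#'
#' Colored noise with power spectral density proportional to
#' `f^-spectral_exponent` is synthesized in the frequency domain, z-scored,
#' and then a stated fraction of samples is removed in contiguous blocks —
#' a stand-in for activity gaps in continuously recorded behavior.
#'
#' @param spectral_exponent Spectral slope (0 = white noise, 2 = red noise).
#' @param duration Total duration (seconds).
#' @param dt Sampling interval (> 0, seconds).
#' @param gap_fraction Fraction of samples removed, in `[0, 1)`.
#' @param seed Integer seed.
#' @param mean_block Mean gap-block length in samples.
#' @return A data frame with columns `time`, `value` (retained samples only);
#'   attribute `"n_total"` records the pre-gap length.
#' @export
gen_gappy_series <- function(spectral_exponent, duration, dt, gap_fraction = 0,
                             seed = 1L, mean_block = 50L) {
  if (dt <= 0) stop("'dt' must be > 0")
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("'gap_fraction' must lie in [0, 1)")
  n <- max(8L, floor(duration / dt))
  rs <- .rng_local(as.integer(seed))
  w <- rs$norm(n)
  fw <- stats::fft(w)
  f <- c(0, seq_len(n - 1L)) / (n * dt)
  f <- pmin(f, (n - f * n * dt) / (n * dt)) # fold to two-sided magnitudes
  f[1L] <- Inf                              # kill DC for negative exponents
  amp <- ifelse(is.finite(f) & f > 0, f^(-spectral_exponent / 2), 0)
  y <- Re(stats::fft(fw * amp, inverse = TRUE)) / n
  y <- as.numeric(scale(y))
  keep <- rep(TRUE, n)
  n_gap <- round(gap_fraction * n)
  guard <- 0L
  while (sum(!keep) < n_gap && guard < 10000L) {
    start <- floor(rs$unif(1L) * n) + 1L
    len <- max(1L, stats::qgeom(rs$unif(1L), 1 / mean_block) + 1L)
    idx <- start:min(n, start + len - 1L)
    keep[idx] <- FALSE
    guard <- guard + 1L
  }
  # trim overshoot so the realized fraction matches the request
  excess <- sum(!keep) - n_gap
  if (excess > 0) keep[which(!keep)[seq_len(excess)]] <- TRUE
  t_all <- (seq_len(n) - 1L) * dt
  structure(data.frame(time = t_all[keep], value = y[keep]),
            n_total = n, class = "data.frame")
}

#' Write / read a behavioral panel as delimited text
#'
#' Panels are stored as tab-separated text with columns `fly_id`, `day`,
#' `n_right`, `n_turns`, `group`; missing fly-days are absent rows.
#'
#' @param panel A `behavioral_panel` data frame.
#' @param path File path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns a
#'   `behavioral_panel` data frame (without latent attributes).
#' @export
write_panel <- function(panel, path) {
  out <- panel[, c("fly_id", "day", "n_right", "n_turns", "group")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x$r_obs <- x$n_right / x$n_turns
  structure(x[, c("fly_id", "day", "n_right", "n_turns", "r_obs", "group")],
            class = c("behavioral_panel", "data.frame"))
}
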