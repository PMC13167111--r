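#' Classify per-frame motion as CCW, CW, radial or stationary
#'
#' Each inter-frame displacement is decomposed into tangential and radial
#' components about the arena center. Displacements slower than `speed_floor`
#' are `stationary`; those whose radial component dominates the tangential
#' one by `tangential_ratio_threshold` are `radial`; the rest are `CCW` or
#' `CW` by the sign of the tangential component (positive = counter-clockwise
#' in standard orientation).
#'
#' @param track A `centroid_track` data frame (columns `time`, `x`, `y`;
#'   attributes `center`, `radius`), e.g. from [gen_circular_walk()].
#' @param speed_floor Minimum speed (mm/s) to count as moving.
#' @param tangential_ratio_threshold Label `radial` when
#'   `|radial| > threshold * |tangential|`.
#' @return Object of class `"motion_labels"`: a factor with levels `CCW`,
#'   `CW`, `radial`, `stationary`, one per displacement, with attribute
#'   `"time"` (midpoint times).
#' @export
classify_motion <- function(track, speed_floor = 1,
                            tangential_ratio_threshold = 1) {
  if (nrow(track) < 2L) stop("track needs at least 2 samples")
  ctr <- attr(track, "center"); if (is.null(ctr)) ctr <- c(0, 0)
  n <- nrow(track)
  dx <- diff(track$x); dy <- diff(track$y); dt <- diff(track$time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  # position relative to center at segment start
  px <- track$x[-n] - ctr[1L]; py <- track$y[-n] - ctr[2L]
  rr <- sqrt(px^2 + py^2)
  speed <- sqrt(dx^2 + dy^2) / dt
  # radial unit (px,py)/r ; tangential (CCW) unit (-py,px)/r
  rad_comp <- ifelse(rr > 0, (dx * px + dy * py) / rr, Inf)
  tan_comp <- ifelse(rr > 0, (-dx * py + dy * px) / rr, 0)
  lab <- rep("radial", n - 1L)
  moving <- speed >= speed_floor
  lab[!moving] <- "stationary"
  turn <- moving & (abs(rad_comp) <= tangential_ratio_threshold * abs(tan_comp))
  lab[turn & tan_comp > 0] <- "CCW"
  lab[turn & tan_comp < 0] <- "CW"
  structure(factor(lab, levels = c("CCW", "CW", "radial", "stationary")),
            time = (track$time[-n] + track$time[-1L]) / 2,
            class = c("motion_labels", "factor"))
}

#' Bin motion labels into a turning-index series
#'
#' Per time bin the turning index is `(N_CCW - N_CW) / (N_CCW + N_CW)`,
#' a signed circling fraction in `[-1, 1]`; bins without directional counts
#' are missing.
#'
#' @param labels A `motion_labels` object (or factor with a `"time"`
#'   attribute).
#' @param bin_width Bin width in seconds (> 0).
#' @return A data frame of class `"turning_series"` with columns `time` (bin
#'   midpoints, s), `value` (turning index or `NA`), `n_ccw`, `n_cw`.
#' @export
turning_index <- function(labels, bin_width) {
  if (bin_width <= 0) stop("'bin_width' must be > 0")
  tm <- attr(labels, "time")
  if (is.null(tm)) stop("labels carry no time attribute")
  bin <- floor(tm / bin_width)
  bins <- seq(min(bin), max(bin))
  n_ccw <- as.numeric(table(factor(bin[labels == "CCW"], levels = bins)))
  n_cw <- as.numeric(table(factor(bin[labels == "CW"], levels = bins)))
  tot <- n_ccw + n_cw
  structure(data.frame(time = (bins + 0.5) * bin_width,
                       value = ifelse(tot > 0, (n_ccw - n_cw) / tot, NA_real_),
                       n_ccw = n_ccw, n_cw = n_cw),
            class = c("turning_series", "data.frame"))
}

#' Blackman-windowed low-pass filter tolerating missing samples
#'
#' Weighted moving average with a Blackman taper spanning `window_hours`.
#' Weights are renormalized over the non-missing samples inside each window;
#' where less than `coverage_floor` of the window's total weight is present,
#' the output is missing. A constant series passes through unchanged (unit DC
#' gain).
#'
#' @param series Data frame with columns `time` (s, regular grid) and `value`
#'   (`NA` = missing).
#' @param window_hours Window span in hours (default 51).
#' @param coverage_floor Minimum present-weight fraction per window.
#' @return The series with `value` replaced by its low-pass filtered version.
#' @export
blackman_lowpass <- function(series, window_hours = 51, coverage_floor = 0.25) {
  if (nrow(series) == 0L) stop("empty series")
  dt <- stats::median(diff(series$time))
  span_s <- window_hours * 3600
  if ((max(series$time) - min(series$time)) < span_s)
    stop("series shorter than the filter window")
  m <- max(3L, round(span_s / dt))
  if (m %% 2L == 0L) m <- m + 1L
  w <- as.numeric(signal::blackman(m))
  v <- series$value
  present <- as.numeric(!is.na(v))
  v0 <- ifelse(is.na(v), 0, v)
  num <- stats::filter(v0, w, sides = 2)
  den <- stats::filter(present, w, sides = 2)
  cov <- den / sum(w)
  out <- as.numeric(num / den)
  # edges (filter returns NA) and low-coverage windows are missing
  out[!is.finite(out) | is.na(cov) | cov < coverage_floor] <- NA_real_
  series$value <- out
  series
}

#' Lomb-Scargle periodogram for unevenly sampled or gappy series
#'
#' Classical Lomb-Scargle periodogram with the phase offset `tau` that makes
#' the sine and cosine terms orthogonal. With `normalization = "psd"` the
#' power at a Fourier frequency of an evenly sampled series equals the
#' classical periodogram `|FFT|^2 / n`; `"standard"` divides by the sample
#' variance.
#'
#' @param series Data frame with columns `time` and `value` (`NA` rows are
#'   dropped; at least 8 finite samples required).
#' @param freq_grid Frequencies (Hz) at which to evaluate; default is a
#'   logarithmic grid from `1/span` to the Nyquist frequency of the median
#'   sampling interval.
#' @param normalization `"psd"` or `"standard"`.
#' @param n_freq Grid size when `freq_grid` is `NULL`.
#' @return A data frame of class `"power_spectrum"` with columns `freq`,
#'   `power`; attribute `"n_samples"`.
#' @export
lomb_scargle <- function(series, freq_grid = NULL,
                         normalization = c("psd", "standard"),
                         n_freq = 200L) {
  normalization <- match.arg(normalization)
  ok <- is.finite(series$value)
  t <- series$time[ok]; y <- series$value[ok]
  if (length(y) < 8L) stop("need at least 8 non-missing samples")
  if (is.null(freq_grid)) {
    span <- max(t) - min(t)
    nyq <- 1 / (2 * stats::median(diff(sort(t))))
    freq_grid <- exp(seq(log(1 / span), log(nyq), length.out = n_freq))
  }
  yc <- y - mean(y)
  om <- 2 * pi * freq_grid
  p <- vapply(om, function(w) {
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2))
  }, numeric(1L))
  if (normalization == "standard") p <- p / stats::var(y)
  structure(data.frame(freq = freq_grid, power = p),
            n_samples = length(y),
            class = c("power_spectrum", "data.frame"))
}

#' Average spectra with bootstrap confidence intervals
#'
#' Per-frequency mean power across series, with pointwise percentile
#' confidence intervals obtained by resampling whole series with replacement.
#'
#' @param spectra List of `power_spectrum` data frames on an identical
#'   frequency grid (>= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return A `power_spectrum` data frame with columns `freq`, `power`,
#'   `ci_lo`, `ci_hi`; attribute `"n_series"`.
#' @export
mean_spectrum_bootstrap <- function(spectra, n_boot = 1000L, level = 0.95,
                                    seed = 1L) {
  if (length(spectra) < 2L) stop("need at least 2 spectra")
  f0 <- spectra[[1L]]$freq
  for (s in spectra)
    if (length(s$freq) != length(f0) || any(s$freq != f0))
      stop("spectra are not on a shared frequency grid")
  mat <- vapply(spectra, function(s) s$power, numeric(length(f0)))
  mat <- matrix(mat, nrow = length(f0))
  rs <- .rng_local(as.integer(seed))
  k <- ncol(mat)
  boots <- matrix(NA_real_, length(f0), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- floor(rs$unif(k) * k) + 1L
    boots[, b] <- rowMeans(mat[, idx, drop = FALSE])
  }
  alpha <- (1 - level) / 2
  qs <- apply(boots, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  structure(data.frame(freq = f0, power = rowMeans(mat),
                       ci_lo = qs[1L, ], ci_hi = qs[2L, ]),
            n_series = k, class = c("power_spectrum", "data.frame"))
}

#' Shuffle control for a gappy series
#'
#' Permutes the non-missing values uniformly among the non-missing
#' timestamps, exactly preserving the marginal distribution while destroying
#' temporal structure (the null against which low-frequency power is judged).
#'
#' @param series Data frame with columns `time`, `value`.
#' @param seed Integer seed.
#' @return The series with non-missing values permuted.
#' @export
shuffle_control <- function(series, seed = 1L) {
  ok <- which(is.finite(series$value))
  if (length(ok) < 2L) stop("need at least 2 non-missing samples")
  rs <- .rng_local(as.integer(seed))
  perm <- order(rs$unif(length(ok)))
  series$value[ok] <- series$value[ok][perm]
  series
}
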