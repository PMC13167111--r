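make_track <- function(x, y, t = seq_along(x) - 1) {
  structure(data.frame(time = t, x = x, y = y),
            center = c(0, 0), radius = 30,
            class = c("centroid_track", "data.frame"))
}

test_that("classify_motion labels arcs, spokes and rests correctly", {
  th <- seq(0, 2 * pi, length.out = 50)
  arc <- make_track(10 * cos(th), 10 * sin(th))
  expect_true(all(classify_motion(arc) == "CCW"))
  arc_cw <- make_track(10 * cos(rev(th)), 10 * sin(rev(th)))
  expect_true(all(classify_motion(arc_cw) == "CW"))
  spoke <- make_track(seq(1, 25, length.out = 10), rep(0, 10))
  expect_true(all(classify_motion(spoke) == "radial"))
  still <- make_track(rep(5, 10) + 1e-4 * (1:10), rep(0, 10))
  expect_true(all(classify_motion(still) == "stationary"))
  # displacement starting at the arena center counts as radial
  ctr <- make_track(c(0, 5), c(0, 0))
  expect_equal(as.character(classify_motion(ctr)), "radial")
})

test_that("turning index is the signed directional fraction", {
  lab <- structure(factor(c(rep("CCW", 30), rep("CW", 10)),
                          levels = c("CCW", "CW", "radial", "stationary")),
                   time = rep(0.5, 40), class = c("motion_labels", "factor"))
  ti <- turning_index(lab, bin_width = 1)
  expect_equal(ti$value, 0.5)
  lab_all <- structure(factor(rep("CCW", 5),
                              levels = c("CCW", "CW", "radial", "stationary")),
                       time = 1:5, class = c("motion_labels", "factor"))
  expect_equal(turning_index(lab_all, 10)$value, 1)
  # equal counts give zero; empty directional bins are missing
  lab_eq <- structure(factor(c("CCW", "CW", "radial"),
                             levels = c("CCW", "CW", "radial", "stationary")),
                      time = c(0.1, 0.2, 5), class = c("motion_labels", "factor"))
  ti_eq <- turning_index(lab_eq, 1)
  expect_equal(ti_eq$value[1], 0)
  expect_true(is.na(ti_eq$value[6]))
})

test_that("turning index is antisymmetric under CW/CCW relabeling", {
  set.seed(10)
  lab <- sample(c("CCW", "CW", "radial"), 200, replace = TRUE)
  flip <- c(CCW = "CW", CW = "CCW", radial = "radial")[lab]
  mk <- function(l) structure(
    factor(l, levels = c("CCW", "CW", "radial", "stationary")),
    time = seq(0.05, 10, length.out = 200),
    class = c("motion_labels", "factor"))
  a <- turning_index(mk(lab), 2)$value
  b <- turning_index(mk(flip), 2)$value
  expect_equal(a, -b)
  expect_true(all(abs(a[!is.na(a)]) <= 1))
})

test_that("Blackman low-pass preserves DC and attenuates fast components", {
  tt <- seq(0, 200 * 3600, by = 3600)
  const <- data.frame(time = tt, value = rep(3.3, length(tt)))
  out <- blackman_lowpass(const)
  expect_equal(out$value[!is.na(out$value)],
               rep(3.3, sum(!is.na(out$value))))
  # 2-hour sinusoid: attenuated by far more than 20 dB
  sine <- data.frame(time = tt, value = sin(2 * pi * tt / (2 * 3600)))
  att <- blackman_lowpass(sine)
  expect_lt(20 * log10(max(abs(att$value), na.rm = TRUE)), -20)
  expect_error(blackman_lowpass(data.frame(time = numeric(), value = numeric())),
               "empty")
})

test_that("windows not touching a gap are unaffected by it", {
  set.seed(2)
  tt <- seq(0, 300 * 3600, by = 3600)
  v <- as.numeric(arima.sim(list(ar = 0.95), length(tt)))
  full <- data.frame(time = tt, value = v)
  gapped <- full
  gapped$value[150:160] <- NA
  a <- blackman_lowpass(full)$value
  b <- blackman_lowpass(gapped)$value
  half <- 26 # window half-width in samples (51 h window, hourly sampling)
  untouched <- setdiff(seq_along(v), (150 - half):(160 + half))
  expect_equal(b[untouched], a[untouched])
})

test_that("Lomb-Scargle matches the classical periodogram on even grids", {
  ser <- sinusoid_series(n = 256, seed = 1)
  n <- 256
  fk <- (1:(n / 2 - 1)) / n
  ls <- lomb_scargle(ser, freq_grid = fk)
  yc <- ser$value - mean(ser$value)
  classical <- (abs(fft(yc))^2 / n)[2:(n / 2)]
  expect_lt(max(abs(ls$power - classical) / classical), 1e-6)
})

test_that("Lomb-Scargle finds an injected peak, even with 30% gaps", {
  ser <- sinusoid_series(n = 512, f0 = 0.09, seed = 3)
  fk <- (1:255) / 512
  expect_equal(lomb_scargle(ser, freq_grid = fk)$freq[
    which.max(lomb_scargle(ser, freq_grid = fk)$power)], 0.08984375,
    tolerance = 0.01)
  set.seed(4)
  keep <- sort(sample(512, round(0.7 * 512)))
  gappy <- ser[keep, ]
  sp <- lomb_scargle(gappy, freq_grid = fk)
  expect_equal(sp$freq[which.max(sp$power)], 0.09, tolerance = 0.01)
  expect_error(lomb_scargle(data.frame(time = 1:5, value = rep(NA_real_, 5))),
               "non-missing")
})

test_that("bootstrap mean spectrum: degenerate and enumerable cases", {
  f <- c(0.1, 0.2, 0.3)
  mk <- function(p) structure(data.frame(freq = f, power = p),
                              class = c("power_spectrum", "data.frame"))
  same <- mean_spectrum_bootstrap(list(mk(1:3), mk(1:3)), n_boot = 200, seed = 1)
  expect_equal(same$power, c(1, 2, 3))
  expect_equal(same$ci_lo, same$ci_hi)
  two <- mean_spectrum_bootstrap(list(mk(c(0, 0, 0)), mk(c(2, 2, 2))),
                                 n_boot = 500, seed = 2)
  expect_equal(two$power, c(1, 1, 1))
  expect_true(all(two$ci_lo %in% c(0, 1, 2)))
  expect_true(all(two$ci_hi %in% c(0, 1, 2)))
  expect_error(mean_spectrum_bootstrap(list(mk(1:3))), "at least 2")
  expect_error(mean_spectrum_bootstrap(list(mk(1:3), structure(
    data.frame(freq = f + 1, power = 1:3),
    class = c("power_spectrum", "data.frame")))), "shared")
})

test_that("bootstrap CIs cover a flat white-noise truth at ~95%", {
  set.seed(5)
  n <- 128
  fk <- (1:(n / 2 - 1)) / n
  spectra <- lapply(1:40, function(i)
    lomb_scargle(data.frame(time = 0:(n - 1), value = rnorm(n)),
                 freq_grid = fk))
  ms <- mean_spectrum_bootstrap(spectra, n_boot = 500, seed = 6)
  truth <- 1 # periodogram of unit white noise has mean sigma^2 = 1
  cover <- mean(ms$ci_lo <= truth & truth <= ms$ci_hi)
  expect_gt(cover, 0.85)
})

test_that("shuffle control preserves the marginal and kills autocorrelation", {
  ser <- ar1_series(n = 512, phi = 0.9, seed = 7)
  sh <- shuffle_control(ser, seed = 8)
  expect_equal(sort(sh$value), sort(ser$value))
  expect_equal(mean(sh$value), mean(ser$value))
  expect_equal(var(sh$value), var(ser$value))
  const <- data.frame(time = 1:10, value = rep(2, 10))
  expect_equal(shuffle_control(const, seed = 1)$value, const$value)
  # lag-1 autocorrelation after shuffling: null-distributed around zero
  r1 <- vapply(1:40, function(s) {
    x <- shuffle_control(ser, seed = 100 + s)$value
    cor(x[-1], x[-512])
  }, numeric(1))
  expect_lt(abs(mean(r1)), 3 * sd(r1) / sqrt(40))
  # missing samples stay missing and in place
  gser <- ser; gser$value[c(3, 50)] <- NA
  gsh <- shuffle_control(gser, seed = 9)
  expect_true(all(is.na(gsh$value[c(3, 50)])))
})

test_that("shuffling destroys low-frequency power of an AR(1) ensemble", {
  ratios <- vapply(1:20, function(s) {
    ser <- ar1_series(n = 256, phi = 0.9, seed = 200 + s)
    lowf <- seq(1 / 256, 0.05, length.out = 12)
    orig <- mean(lomb_scargle(ser, freq_grid = lowf)$power)
    shuf <- mean(lomb_scargle(shuffle_control(ser, seed = 300 + s),
                              freq_grid = lowf)$power)
    orig / shuf
  }, numeric(1))
  expect_gt(mean(ratios), 2)
})
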