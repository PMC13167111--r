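#' Generate a band-limited random environment series
#'
#' White noise is filtered in the frequency domain with a hard (boxcar) mask
#' retaining components whose period lies in `period_band_days`, inverse
#' transformed, z-scored, and scaled to standard deviation `sigma_mean` —
#' the surrogate environmental optimum series driving selection.
#'
#' @param period_band_days Length-2 vector `(period_low, period_high)` in
#'   days, `2 <= period_low < period_high <= length_days`.
#' @param sigma_mean Amplitude: the s.d. the normalized series is scaled to.
#' @param length_days Series length in days.
#' @param seed Integer seed.
#' @return Data frame of class `"environment_series"` with columns `day`,
#'   `value`; attributes `sigma_mean`, `band`, `source`.
#' @export
gen_filtered_noise <- function(period_band_days, sigma_mean, length_days,
                               seed = 1L) {
  n <- as.integer(length_days)
  lo <- period_band_days[1L]; hi <- period_band_days[2L]
  if (!(lo < hi)) stop("'period_band_days' must be increasing")
  if (hi > n) stop("band period exceeds series length")
  if (lo < 2) stop("band period below the 2-day resolution limit")
  rs <- .rng_local(as.integer(seed))
  w <- rs$norm(n)
  fw <- stats::fft(w)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) / n            # cycles per day, two-sided
  period <- ifelse(f > 0, 1 / f, Inf)
  mask <- period >= lo & period <= hi
  if (!any(mask)) stop("no resolvable frequency inside the band")
  y <- Re(stats::fft(fw * mask, inverse = TRUE)) / n
  y <- (y - mean(y)) / stats::sd(y) * sigma_mean
  structure(data.frame(day = seq_len(n), value = y),
            sigma_mean = sigma_mean, band = c(lo, hi), source = "synthetic",
            class = c("environment_series", "data.frame"))
}

#' Preprocess a real daily series into model-ready environment windows
#'
#' Implements the eligibility and normalization pipeline for observational
#' daily series: segments containing no missing run longer than `max_gap`
#' days are identified, short gaps are filled by linear interpolation,
#' non-overlapping `window`-day stretches are sampled at random among
#' eligible starts (greedy, no data point reused), and each window is
#' z-scored then scaled to s.d. `sigma_mean`.
#'
#' @param raw Data frame with columns `date` (`Date`, unique, sorted) and
#'   `value`.
#' @param window Window length in days (default 1000).
#' @param max_gap Longest permissible missing run, days (default 5).
#' @param sigma_mean Amplitude to scale each window to.
#' @param seed Integer seed for the window sampling order.
#' @return List of `environment_series` (possibly empty, with a notice);
#'   each carries attributes `sigma_mean`, `source` (start/end dates).
#' @export
preprocess_real <- function(raw, window = 1000L, max_gap = 5L, sigma_mean = 0.2,
                            seed = 1L) {
  if (is.unsorted(raw$date, strictly = TRUE)) stop("dates must be unique and sorted")
  ok <- is.finite(raw$value)
  raw <- raw[ok, , drop = FALSE]   # treat non-finite rows as absent dates
  if (nrow(raw) == 0L) { message("no data"); return(list()) }
  d <- as.integer(raw$date)
  gap <- diff(d) - 1L              # missing days between consecutive records
  # split into segments at gaps exceeding max_gap
  seg_id <- cumsum(c(0L, as.integer(gap > max_gap)))
  out <- list()
  taken <- 0L
  rs <- .rng_local(as.integer(seed))
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    days <- d[idx[1L]]:d[idx[length(idx)]]
    if (length(days) < window) next
    v <- stats::approx(d[idx], raw$value[idx], xout = days)$y
    n_start <- length(days) - window + 1L
    starts <- seq_len(n_start)
    used <- rep(FALSE, length(days))
    order_ <- order(rs$unif(n_start))
    for (st in starts[order_]) {
      span <- st:(st + window - 1L)
      if (any(used[span])) next
      used[span] <- TRUE
      z <- v[span]
      z <- (z - mean(z)) / stats::sd(z) * sigma_mean
      out[[length(out) + 1L]] <- structure(
        data.frame(day = seq_len(window), value = z),
        sigma_mean = sigma_mean, band = NULL,
        source = paste(as.Date(days[span[1L]], origin = "1970-01-01"),
                       as.Date(days[span[window]], origin = "1970-01-01"),
                       sep = "/"),
        class = c("environment_series", "data.frame"))
    }
  }
  if (!length(out)) message("no eligible ", window, "-day window")
  out
}

#' Aggregate a sub-daily series to daily mean, max and min
#'
#' @param sub Data frame with columns `timestamp` (`POSIXct` or anything
#'   `as.Date` can handle) and `value`.
#' @return Named list of three data frames (`mean`, `max`, `min`), each with
#'   columns `date`, `value`; days without observations are absent.
#' @export
daily_aggregate <- function(sub) {
  dt <- as.Date(sub$timestamp)
  ok <- is.finite(sub$value)
  dt <- dt[ok]; v <- sub$value[ok]
  agg <- function(fun) {
    r <- stats::aggregate(v, by = list(date = dt), FUN = fun)
    names(r)[2L] <- "value"
    r[order(r$date), , drop = FALSE]
  }
  list(mean = agg(mean), max = agg(max), min = agg(min))
}

#' Write / read an environment series as delimited text
#'
#' Two tab-separated columns (`day`, `value`) preceded by commented metadata
#' lines (`# sigma_mean:`, `# band:`, `# source:`), which `read_series`
#' restores.
#'
#' @param env An `environment_series` data frame.
#' @param path File path.
#' @return `write_series` returns `path` invisibly; `read_series` an
#'   `environment_series`.
#' @export
write_series <- function(env, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sigma_mean: ", attr(env, "sigma_mean")),
    paste0("# band: ", paste(attr(env, "band"), collapse = ",")),
    paste0("# source: ", attr(env, "source"))), con)
  utils::write.table(env, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "# ")]
  get <- function(key) {
    ln <- meta[startsWith(meta, paste0("# ", key, ":"))]
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, ": ?"), "", ln[1L])
  }
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  band <- get("band")
  structure(x,
            sigma_mean = as.numeric(get("sigma_mean")),
            band = if (nzchar(band %||% "")) as.numeric(strsplit(band, ",")[[1L]]) else NULL,
            source = get("source"),
            class = c("environment_series", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
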