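#' Remove non-wear temperature readings below a skin-contact floor
#'
#' Wrist loggers are taken off for showering and bathing; off-wrist readings
#' fall towards ambient temperature. Every value strictly below `floor`
#' (default 28 degC) is treated as non-wear and replaced by the temporally
#' nearest retained value; when the two nearest retained neighbours are
#' equidistant the earlier one wins. Values equal to the floor are kept.
#'
#' @param raw a [temperature_series()].
#' @param floor skin-contact floor in degC; readings strictly below it are
#'   replaced. Default 28.
#'
#' @return A `temperature_series` of the same length with `cleaned = TRUE`.
#' @export
#' @examples
#' t0 <- as.POSIXct("2024-01-01 15:00:00", tz = "UTC")
#' clean_temperature(temperature_series(t0, 300, c(34.0, 27.5, 34.4)))$values
clean_temperature <- function(raw, floor = 28) {
  stopifnot(inherits(raw, "temperature_series"))
  x <- raw$values
  bad <- !is.finite(x) | x < floor
  if (all(bad))
    stop("unrecoverable temperature series: every reading is below ",
         floor, " degC (or non-finite); no retained value to interpolate from",
         call. = FALSE)
  if (any(bad)) {
    n <- length(x)
    valid <- which(!bad)
    # index of previous / next retained sample for every position
    prev <- cummax(ifelse(bad, 0L, seq_len(n)))
    prev[prev == 0L] <- NA_integer_
    nxt <- rev(cummin(rev(ifelse(bad, n + 1L, seq_len(n)))))
    nxt[nxt > n] <- NA_integer_
    i <- which(bad)
    d_prev <- i - prev[i]
    d_next <- nxt[i] - i
    use_prev <- !is.na(d_prev) & (is.na(d_next) | d_prev <= d_next)
    src <- ifelse(use_prev, prev[i], nxt[i])
    x[i] <- x[src]
  }
  temperature_series(raw$start, raw$step, x, cleaned = TRUE)
}

#' Median-smooth a temperature series
#'
#' Running median with an odd, centred window (default 3), suppressing
#' single-sample spikes left by the logger or by non-wear interpolation
#' edges. The `(window - 1) / 2` samples at each end are copied unchanged.
#'
#' @param series a cleaned [temperature_series()].
#' @param window odd window size, at least 3.
#'
#' @return A smoothed `temperature_series`, same length, still cleaned.
#' @export
median_smooth <- function(series, window = 3L) {
  stopifnot(inherits(series, "temperature_series"))
  if (!series$cleaned)
    stop("smooth after cleaning: run clean_temperature() first", call. = FALSE)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  if (window > length(series$values))
    stop("`window` larger than the series", call. = FALSE)
  sm <- as.numeric(stats::runmed(series$values, window, endrule = "keep"))
  temperature_series(series$start, series$step, sm, cleaned = TRUE)
}

#' Segment a recording into 3 PM-anchored days
#'
#' Sleep analysis windows run 3 PM to 3 PM so that each window contains one
#' full night plus any daytime naps. All windows intersecting the recording
#' are returned; a window is `complete` when every expected sample
#' (`24 h / step`, i.e. 288 at 5-min sampling) is present. Rhythm statistics
#' downstream use complete windows only by default.
#'
#' @param series a cleaned [temperature_series()].
#' @param anchor_hour local hour at which windows start (default 15).
#'
#' @return data.frame with one row per window: `window_start`, `window_end`,
#'   `first_index`, `last_index` (1-based range into the series, NA when the
#'   window holds no sample), `n_samples`, `complete`.
#' @export
segment_days <- function(series, anchor_hour = 15L) {
  stopifnot(inherits(series, "temperature_series"))
  tt <- as.numeric(series_times(series))
  expected <- 86400 / series$step
  if (expected != round(expected))
    stop("sampling step must divide the day evenly", call. = FALSE)
  t0 <- tt[1L]; t1 <- tt[length(tt)]
  first_ws <- floor((t0 - anchor_hour * 3600) / 86400) * 86400 +
    anchor_hour * 3600
  ws <- seq(first_ws, t1, by = 86400)
  rows <- lapply(ws, function(w) {
    inside <- which(tt >= w & tt < w + 86400)
    n <- length(inside)
    data.frame(
      window_start = as.POSIXct(w, origin = "1970-01-01", tz = .tz),
      window_end = as.POSIXct(w + 86400, origin = "1970-01-01", tz = .tz),
      first_index = if (n) inside[1L] else NA_integer_,
      last_index = if (n) inside[n] else NA_integer_,
      n_samples = n,
      complete = n == expected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# samples of a series restricted to complete anchored days; errors when none
complete_day_values <- function(series, anchor_hour = 15L) {
  seg <- segment_days(series, anchor_hour)
  seg <- seg[seg$complete, , drop = FALSE]
  if (nrow(seg) == 0L)
    stop("no complete ", anchor_hour, ":00-anchored day in the recording",
         call. = FALSE)
  idx <- unlist(Map(seq, seg$first_index, seg$last_index), use.names = FALSE)
  list(values = series$values[idx],
       times = series_times(series)[idx],
       n_days = nrow(seg))
}

#' Sleep/wake temperature means and contrast
#'
#' Splits the samples of a cleaned series by reference sleep intervals and
#' returns the mean wrist temperature asleep, awake, and their difference
#' (sleep minus wake). The contrast shrinks with age and dementia and is the
#' study's summary of circadian thermoregulatory range.
#'
#' @param series a cleaned [temperature_series()].
#' @param sleep a [sleep_intervals()] table (or any data.frame with `onset`,
#'   `offset` `POSIXct` columns). Samples with `onset <= t < offset` of any
#'   interval count as sleep.
#'
#' @return list with `mean_sleep_temp`, `mean_wake_temp`, `sleep_wake_diff`
#'   (all degC), and the sample counts `n_sleep`, `n_wake`.
#' @export
sleep_wake_means <- function(series, sleep) {
  stopifnot(inherits(series, "temperature_series"))
  if (!series$cleaned)
    stop("series must be cleaned before computing sleep/wake means",
         call. = FALSE)
  if (!is.data.frame(sleep) || nrow(sleep) == 0L)
    stop("no sleep intervals supplied: sleep mean undefined", call. = FALSE)
  tt <- as.numeric(series_times(series))
  in_sleep <- rep(FALSE, length(tt))
  for (k in seq_len(nrow(sleep))) {
    in_sleep <- in_sleep |
      (tt >= as.numeric(sleep$onset[k]) & tt < as.numeric(sleep$offset[k]))
  }
  if (!any(in_sleep))
    stop("no temperature samples fall inside the sleep intervals",
         call. = FALSE)
  if (all(in_sleep))
    stop("no temperature samples fall outside the sleep intervals",
         call. = FALSE)
  ms <- mean(series$values[in_sleep])
  mw <- mean(series$values[!in_sleep])
  list(mean_sleep_temp = ms, mean_wake_temp = mw, sleep_wake_diff = ms - mw,
       n_sleep = sum(in_sleep), n_wake = sum(!in_sleep))
}

# chronological bin-mean sequence on an absolute clock-aligned grid, plus
# each bin's time-of-day index (for pooling into a 24-h profile)
bin_sequence <- function(values, times, bin_width) {
  n_bins <- 86400 / bin_width
  if (n_bins != round(n_bins))
    stop("`bin_width` must divide 24 h evenly", call. = FALSE)
  key <- floor(as.numeric(times) / bin_width)
  m <- tapply(values, key, mean)
  abs_bin <- as.numeric(names(m))
  list(mean = as.numeric(m), bin_of_day = abs_bin %% n_bins)
}

#' Interday stability (IS)
#'
#' Nonparametric measure of how consistently the 24-h temperature profile
#' repeats from day to day. The series (complete 3 PM-anchored days only) is
#' first reduced to chronological bin means X_1..X_N at `bin_width`
#' resolution (hourly means by convention); with Xbar_h the time-of-day
#' profile mean of bin-of-day h pooled across days,
#' \deqn{IS = \frac{N \sum_h (\bar X_h - \bar X)^2}{n_{bins} \sum_i (X_i - \bar X)^2}.}
#' IS is 1 for a signal that repeats exactly with 24-h period and has
#' expectation about n_bins/N for white noise. Setting `bin_width` to the
#' sampling step makes the binning the identity, so the formula then acts on
#' the raw samples.
#'
#' @param series a cleaned [temperature_series()] covering at least 2 complete
#'   anchored days.
#' @param bin_width time-of-day bin width in seconds. Default 3600 (hourly
#'   means, the conventional resolution); set to the sampling step for a
#'   full-resolution variant.
#'
#' @return IS, dimensionless in \[0, 1\].
#' @export
interday_stability <- function(series, bin_width = 3600) {
  stopifnot(inherits(series, "temperature_series"))
  if (!series$cleaned) stop("series must be cleaned", call. = FALSE)
  cd <- complete_day_values(series)
  if (cd$n_days < 2L)
    stop("interday stability needs at least 2 complete days", call. = FALSE)
  bs <- bin_sequence(cd$values, cd$times, bin_width)
  x <- bs$mean
  xbar <- mean(x)
  ss_tot <- sum((x - xbar)^2)
  if (ss_tot == 0)
    stop("constant series: interday stability is undefined (0/0)",
         call. = FALSE)
  prof <- as.numeric(tapply(x, bs$bin_of_day, mean))
  n_bins <- length(prof)
  length(x) * sum((prof - xbar)^2) / (n_bins * ss_tot)
}

#' Intraday variability (IV)
#'
#' Nonparametric measure of the hour-to-hour fragmentation of the daily
#' profile: the mean squared successive difference of the chronological
#' bin-mean sequence relative to its variance,
#' \deqn{IV = \frac{n \sum_{i=2}^n (x_i - x_{i-1})^2}{(n-1) \sum_i (x_i - \bar x)^2}.}
#' IV is near 0 for a smooth sinusoidal rhythm (the hourly-sampled 24-h
#' cosine gives about (2*pi/24)^2), about 2 for white noise, and up to 4 for
#' a sequence alternating between two levels.
#'
#' @inheritParams interday_stability
#'
#' @return IV, dimensionless, non-negative.
#' @export
intraday_variability <- function(series, bin_width = 3600) {
  stopifnot(inherits(series, "temperature_series"))
  if (!series$cleaned) stop("series must be cleaned", call. = FALSE)
  cd <- complete_day_values(series)
  xs <- bin_sequence(cd$values, cd$times, bin_width)$mean
  n <- length(xs)
  if (n < 2L)
    stop("intraday variability needs at least 2 bins", call. = FALSE)
  ss <- sum((xs - mean(xs))^2)
  if (ss == 0)
    stop("constant bin means: intraday variability is undefined (0/0)",
         call. = FALSE)
  n * sum(diff(xs)^2) / ((n - 1) * ss)
}

#' Single-component cosinor fit
#'
#' Ordinary least squares of the 24-h cosine model
#' `y(t) = M + beta * cos(w t) + gamma * sin(w t)` with `w = 2*pi/24` per
#' hour and `t` in hours since local midnight, fitted on complete
#' 3 PM-anchored days. The rhythm-adjusted mean (MESOR) is `M`, the amplitude
#' is `sqrt(beta^2 + gamma^2)` (half the peak-to-trough range), and the
#' acrophase is the clock time of the fitted maximum, reported in minutes
#' after local midnight in \[0, 1440).
#'
#' @param series a cleaned [temperature_series()] with at least one complete
#'   anchored day.
#'
#' @return list of class `cosinor_fit`: `mesor`, `amplitude` (degC),
#'   `acrophase_min` (minutes after midnight, `NA` when the amplitude is
#'   numerically 0), `residual_sd`, `n`.
#' @export
cosinor_fit <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  if (!series$cleaned) stop("series must be cleaned", call. = FALSE)
  cd <- complete_day_values(series)
  th <- (as.numeric(cd$times) %% 86400) / 3600  # hours since local midnight
  w <- 2 * pi / 24
  X <- cbind(1, cos(w * th), sin(w * th))
  fit <- stats::lm.fit(X, cd$values)
  beta <- fit$coefficients[2L]
  gam <- fit$coefficients[3L]
  amp <- sqrt(beta^2 + gam^2)
  acro <- if (amp < 1e-12) NA_real_ else {
    ((atan2(gam, beta) / w) %% 24) * 60
  }
  dfree <- length(cd$values) - 3L
  out <- list(mesor = unname(fit$coefficients[1L]), amplitude = unname(amp),
              acrophase_min = unname(acro),
              residual_sd = sqrt(sum(fit$residuals^2) / max(dfree, 1L)),
              n = length(cd$values))
  class(out) <- "cosinor_fit"
  out
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> MESOR %.2f degC, amplitude %.2f degC, acrophase %s\n",
    x$mesor, x$amplitude,
    if (is.na(x$acrophase_min)) "undefined (flat fit)"
    else sprintf("%02d:%02d (%.0f min after midnight)",
                 floor(x$acrophase_min / 60) %% 24,
                 floor(x$acrophase_min %% 60), x$acrophase_min)))
  invisible(x)
}

#' Per-subject rhythm summary
#'
#' Runs the full temperature pipeline on a raw series — cleaning, median
#' smoothing, sleep/wake contrast against reference intervals, IS, IV and the
#' cosinor fit — and returns one summary row.
#'
#' @param raw a raw [temperature_series()].
#' @param sleep reference [sleep_intervals()].
#' @param bin_width IS/IV time-of-day bin width in seconds (default hourly).
#' @param floor cleaning floor in degC.
#'
#' @return one-row data.frame: `mean_sleep_temp`, `mean_wake_temp`,
#'   `sleep_wake_diff`, `is_value`, `iv_value`, `mesor`, `amplitude`,
#'   `acrophase_min`, `n_complete_days`.
#' @export
rhythm_summary <- function(raw, sleep, bin_width = 3600, floor = 28) {
  cleaned <- if (inherits(raw, "temperature_series") && raw$cleaned) raw
             else median_smooth(clean_temperature(raw, floor = floor))
  sw <- sleep_wake_means(cleaned, sleep)
  cf <- cosinor_fit(cleaned)
  data.frame(
    mean_sleep_temp = sw$mean_sleep_temp,
    mean_wake_temp = sw$mean_wake_temp,
    sleep_wake_diff = sw$sleep_wake_diff,
    is_value = interday_stability(cleaned, bin_width),
    iv_value = intraday_variability(cleaned, bin_width),
    mesor = cf$mesor, amplitude = cf$amplitude,
    acrophase_min = cf$acrophase_min,
    n_complete_days = complete_day_values(cleaned)$n_days)
}
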