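# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

t15 <- function(date = "2024-03-04") {
  as.POSIXct(paste(date, "15:00:00"), tz = "UTC")
}

# cleaned series from raw values (step in seconds), starting 15:00
mk_series <- function(values, step = 300, start = t15(), cleaned = TRUE) {
  temperature_series(start, step, values, cleaned = cleaned)
}

# pure 24-h cosinor signal sampled over whole anchored days
mk_cosinor_series <- function(mesor, amplitude, acrophase_min, n_days,
                              step = 300, noise_sd = 0, start = t15()) {
  n <- n_days * 86400 / step
  tt <- as.numeric(start) + (seq_len(n) - 1) * step
  tod_min <- (tt %% 86400) / 60
  y <- mesor + amplitude * cos(2 * pi * (tod_min - acrophase_min) / 1440)
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  mk_series(y, step = step, start = start)
}

# literal index-by-index transcription of the IS formula on the bin-mean
# sequence: independent of the package's vectorized path
is_oracle <- function(values, times, bin_width) {
  key <- floor(as.numeric(times) / bin_width)
  uk <- sort(unique(key))
  x <- numeric(length(uk))
  for (j in seq_along(uk)) {
    s <- 0; m <- 0
    for (i in seq_along(values)) {
      if (key[i] == uk[j]) { s <- s + values[i]; m <- m + 1 }
    }
    x[j] <- s / m
  }
  n_bins <- 86400 / bin_width
  hod <- uk %% n_bins
  uh <- sort(unique(hod))
  xbar <- 0
  for (i in seq_along(x)) xbar <- xbar + x[i]
  xbar <- xbar / length(x)
  num <- 0
  for (h in uh) {
    s <- 0; m <- 0
    for (i in seq_along(x)) if (hod[i] == h) { s <- s + x[i]; m <- m + 1 }
    num <- num + (s / m - xbar)^2
  }
  den <- 0
  for (i in seq_along(x)) den <- den + (x[i] - xbar)^2
  length(x) * num / (length(uh) * den)
}

# literal transcription of the IV formula on the bin-mean sequence
iv_oracle <- function(values, times, bin_width) {
  key <- floor(as.numeric(times) / bin_width)
  uk <- sort(unique(key))
  x <- numeric(length(uk))
  for (j in seq_along(uk)) {
    s <- 0; m <- 0
    for (i in seq_along(values)) {
      if (key[i] == uk[j]) { s <- s + values[i]; m <- m + 1 }
    }
    x[j] <- s / m
  }
  n <- length(x)
  xbar <- 0
  for (i in seq_len(n)) xbar <- xbar + x[i]
  xbar <- xbar / n
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  n * num / ((n - 1) * den)
}

# exhaustive label-permutation oracle for the one-tailed t test
perm_oracle_p <- function(a, b, direction = "a_greater") {
  pooled <- c(a, b)
  na <- length(a)
  alt <- if (direction == "a_greater") "greater" else "less"
  tobs <- stats::t.test(a, b, alternative = alt)$statistic
  idx <- utils::combn(length(pooled), na)
  ts <- apply(idx, 2, function(i)
    stats::t.test(pooled[i], pooled[-i], alternative = alt)$statistic)
  if (direction == "a_greater") mean(ts >= tobs - 1e-12)
  else mean(ts <= tobs + 1e-12)
}

# accel series that is perfectly still except for listed movement windows
mk_still_accel <- function(n_hours, rate = 2, start = t15(),
                           move = NULL, move_amp = 0.3) {
  n <- n_hours * 3600 * rate
  vals <- cbind(numeric(n), numeric(n), rep(1, n))
  if (!is.null(move)) {
    tt <- as.numeric(start) + (seq_len(n) - 1) / rate
    for (k in seq_len(nrow(move))) {
      ii <- which(tt >= as.numeric(move$start[k]) &
                    tt < as.numeric(move$end[k]))
      vals[ii, ] <- vals[ii, ] + matrix(rnorm(3 * length(ii), 0, move_amp),
                                        ncol = 3)
    }
  }
  accel_series(start, rate, vals)
}

# minute-resolution clock helper: "HH:MM" on a date (+days)
clk <- function(hm, date = "2024-03-04", add_days = 0) {
  as.POSIXct(paste(date, paste0(hm, ":00")), tz = "UTC") + add_days * 86400
}

# signed minutes after midnight in (-720, 720], for clock-time averaging
min_after_midnight <- function(t) {
  ((as.numeric(t) / 60) %% 1440 + 720) %% 1440 - 720
}
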