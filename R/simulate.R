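# Synthetic wearable-data generator.
#
# All randomness flows through one explicit seed; the caller's RNG state is
# untouched. The recording starts at 15:00 local so every simulated day is a
# complete 3 PM-anchored window.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate one synthetic subject
#'
#' Simulates a multi-day wearable recording with known ground truth for one
#' sleeper phenotype: a wrist-temperature series (5-min sampling), raw
#' tri-axial accelerometry, a nightly self-report journal, a 30-min caregiver
#' observation sheet, and the ground-truth sleep structure the signals were
#' built from.
#'
#' The temperature model is additive: a 24-h cosine (MESOR, amplitude,
#' acrophase) plus a sleep-state elevation obtained by smoothing the sleep
#' indicator with a symmetric exponential kernel (time constant
#' `transition_tau`, so temperature starts rising shortly before onset and
#' decays after offset), plus iid Gaussian noise. Because sleep always falls
#' at a similar circadian phase, the cosine and the sleep indicator are
#' correlated; the elevation coefficient and baseline are therefore
#' calibrated per realization so that the noise-free sleep and wake means
#' equal `sleep_temp` and `wake_temp` exactly. Shower events force the
#' temperature to `shower_temp` (below the 28 degC wear floor) for 10-20 min.
#'
#' Accelerometry carries gravity as a constant 1 g on the z axis plus sensor
#' noise. Wake epochs always contain low-level postural jitter plus
#' intermittent Poisson movement bursts; sleep is near-static except for
#' phenotype-specific injected movement: `periodic_30s` adds a brief burst
#' about every 30 s during a `movement_window_h`-hour window after each
#' onset; `fragmented` breaks each sleep interval into static episodes
#' shorter than `fragment_episode_max` minutes separated by movement bouts.
#'
#' @param config a [phenotype_config()].
#' @param n_days number of simulated 24-h days (>= 1).
#' @param seed integer seed; identical calls are byte-identical.
#' @param accel_rate accelerometer rate in Hz (default 25; the day must
#'   contain a whole number of samples). Lower rates give the same epoch
#'   statistics and much smaller outputs.
#' @param temp_step temperature sampling interval in seconds (default 300).
#' @param transition_tau temperature transition time constant, seconds
#'   (default 1800).
#' @param shower_temp forced off-wrist temperature in degC (default 25).
#' @param movement_window_h length of the periodic-movement window in hours
#'   (default 2.5).
#' @param start_date local calendar date of the first recording day.
#'
#' @return list of class `synthetic_subject` with elements `temperature`
#'   ([temperature_series()]), `accel` ([accel_series()]), `journal`
#'   ([sleep_journal()], source `"self_report"`), `sheet`
#'   ([observation_sheet()]), `truth` (list: `sleep_intervals`,
#'   `movement_epochs`, `shower_gaps`), and `config`.
#' @export
#' @examples
#' sub <- generate_subject(phenotype_config("regular_young"), n_days = 2,
#'                         seed = 1, accel_rate = 1)
#' sub$journal
generate_subject <- function(config, n_days, seed, accel_rate = 25,
                             temp_step = 300, transition_tau = 1800,
                             shower_temp = 25, movement_window_h = 2.5,
                             start_date = as.Date("2024-03-04")) {
  stopifnot(inherits(config, "phenotype_config"))
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L)
    stop("`n_days` must be a positive integer", call. = FALSE)
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  if (86400 %% temp_step != 0)
    stop("`temp_step` must divide the 86400-s day evenly", call. = FALSE)
  spd_acc <- 86400 * accel_rate
  if (abs(spd_acc - round(spd_acc)) > 1e-9)
    stop("`accel_rate` must give a whole number of samples per day",
         call. = FALSE)
  with_local_seed(seed, {
    t0 <- as.POSIXct(paste(start_date, "15:00:00"), tz = .tz)
    t0n <- as.numeric(t0)
    total_s <- n_days * 86400

    truth <- simulate_sleep_structure(config, n_days, t0n, total_s,
                                      movement_window_h)
    temp <- simulate_temperature(config, truth, t0, t0n, total_s, temp_step,
                                 transition_tau, shower_temp)
    accel <- simulate_accel(config, truth, t0, t0n, total_s, accel_rate)
    journal <- simulate_journal(config, truth, t0n)
    sheet <- simulate_sheet(config, truth, t0n, total_s)

    structure(list(temperature = temp$series, accel = accel,
                   journal = journal, sheet = sheet,
                   truth = list(sleep_intervals = truth$intervals,
                                movement_epochs = truth$movement,
                                shower_gaps = temp$shower_gaps),
                   config = config),
              class = "synthetic_subject")
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "<synthetic_subject> %s, %d nights, %d temperature samples, %d accel samples\n",
    x$config$name, nrow(x$journal), length(x$temperature$values),
    nrow(x$accel$values)))
  invisible(x)
}

# --- sleep structure ------------------------------------------------------

simulate_sleep_structure <- function(config, n_days, t0n, total_s,
                                     movement_window_h) {
  onset_clk <- parse_clock(config$mean_onset)   # s after midnight
  offset_clk <- parse_clock(config$mean_offset)
  onsets <- offsets <- numeric(n_days)
  for (k in seq_len(n_days)) {
    day0 <- t0n - 15 * 3600 + (k - 1) * 86400   # midnight starting day k
    # evening onsets (>= 15:00) fall on day k, post-midnight onsets on day k+1
    nominal_on <- day0 + onset_clk + if (onset_clk < 15 * 3600) 86400 else 0
    nominal_off <- day0 + 86400 + offset_clk
    onsets[k] <- nominal_on + stats::rnorm(1, 0, config$onset_sd * 60)
    offsets[k] <- nominal_off + stats::rnorm(1, 0, config$offset_sd * 60)
    # keep the night inside its anchored day and non-degenerate
    onsets[k] <- max(onsets[k], day0 + 15 * 3600 + 600)
    offsets[k] <- min(max(offsets[k], onsets[k] + 3600),
                      day0 + 86400 + 15 * 3600 - 600)
  }
  kinds <- rep("main", n_days)
  night <- seq_len(n_days)

  # daytime naps on the afternoon following each night
  if (config$nap_rate > 0) {
    for (k in seq_len(n_days)) {
      for (j in seq_len(stats::rpois(1, config$nap_rate))) {
        ns <- t0n - 15 * 3600 + k * 86400 + stats::runif(1, 12, 14.5) * 3600
        ne <- ns + stats::runif(1, 20, 60) * 60
        ne <- min(ne, t0n + total_s - 60)
        # disjoint from everything drawn so far
        if (ns >= ne) next
        if (any(ns < offsets & ne > onsets)) next
        onsets <- c(onsets, ns); offsets <- c(offsets, ne)
        kinds <- c(kinds, "nap"); night <- c(night, k)
      }
    }
  }
  o <- order(onsets)
  intervals <- sleep_intervals(
    as.POSIXct(onsets[o], origin = "1970-01-01", tz = .tz),
    as.POSIXct(offsets[o], origin = "1970-01-01", tz = .tz),
    kind = kinds[o])

  movement <- data.frame(start = numeric(0), end = numeric(0),
                         night = integer(0))
  main_on <- onsets[seq_len(n_days)]
  main_off <- offsets[seq_len(n_days)]
  if (config$movement_mode == "periodic_30s") {
    we <- pmin(main_on + movement_window_h * 3600, main_off)
    movement <- data.frame(start = main_on, end = we, night = seq_len(n_days))
  } else if (config$movement_mode == "fragmented") {
    # every sleep interval (nights and naps) is broken into static episodes
    # each strictly shorter than fragment_episode_max, separated by movement
    # bouts long enough (12-25 min) that no downstream merge rule can fuse
    # the episodes back into one consolidated period
    mx <- config$fragment_episode_max
    for (k in seq_along(onsets)) {
      t <- onsets[k]
      repeat {
        t <- t + stats::runif(1, 60 * max(mx / 6, 1), 60 * (mx - 5))
        if (t >= offsets[k] - 120) break
        bout <- stats::runif(1, 720, 1500)
        bout <- min(bout, offsets[k] - t)
        movement <- rbind(movement,
                          data.frame(start = t, end = t + bout,
                                     night = night[k]))
        t <- t + bout
      }
    }
  }
  movement$start_time <- as.POSIXct(movement$start, origin = "1970-01-01",
                                    tz = .tz)
  movement$end_time <- as.POSIXct(movement$end, origin = "1970-01-01",
                                  tz = .tz)
  list(intervals = intervals, movement = movement,
       onsets = onsets[o], offsets = offsets[o], kinds = kinds[o],
       night = night[o], n_days = n_days)
}

# --- temperature ----------------------------------------------------------

# symmetric exponential smoothing of a 0/1 indicator (forward + backward
# first-order filters averaged): rise starts before onset, decay after offset
smooth_indicator <- function(s, dt, tau) {
  a <- exp(-dt / tau)
  n <- length(s)
  fwd <- numeric(n); bwd <- numeric(n)
  fwd[1] <- s[1]
  for (i in 2:n) fwd[i] <- a * fwd[i - 1] + (1 - a) * s[i]
  bwd[n] <- s[n]
  for (i in (n - 1):1) bwd[i] <- a * bwd[i + 1] + (1 - a) * s[i]
  (fwd + bwd) / 2
}

in_any_interval <- function(tt, starts, ends) {
  out <- rep(FALSE, length(tt))
  for (k in seq_along(starts))
    out <- out | (tt >= starts[k] & tt < ends[k])
  out
}

simulate_temperature <- function(config, truth, t0, t0n, total_s, temp_step,
                                 transition_tau, shower_temp) {
  n <- total_s / temp_step
  tt <- t0n + (seq_len(n) - 1) * temp_step
  asleep <- in_any_interval(tt, truth$onsets, truth$offsets)
  s_filt <- smooth_indicator(as.numeric(asleep), temp_step, transition_tau)
  tod_min <- (tt %% 86400) / 60
  cosc <- config$cosinor_amplitude *
    cos(2 * pi * (tod_min - config$cosinor_acrophase) / 1440)

  contrast <- config$sleep_temp - config$wake_temp
  mS <- mean(s_filt[asleep]); mW <- mean(s_filt[!asleep])
  cS <- mean(cosc[asleep]); cW <- mean(cosc[!asleep])
  elev_coef <- (contrast - (cS - cW)) / (mS - mW)
  base <- config$wake_temp - cW - elev_coef * mW
  y <- base + cosc + elev_coef * s_filt +
    stats::rnorm(n, 0, config$temp_noise_sd)

  # shower/bath excursions: off-wrist readings below the wear floor,
  # sample-aligned so gap ranges match forced samples exactly
  gaps <- data.frame(start = as.POSIXct(numeric(0), origin = "1970-01-01",
                                        tz = .tz),
                     end = as.POSIXct(numeric(0), origin = "1970-01-01",
                                      tz = .tz))
  if (config$shower_rate > 0) {
    mains <- which(truth$kinds == "main")
    for (k in seq_along(mains)) {
      for (j in seq_len(stats::rpois(1, config$shower_rate))) {
        gs <- truth$offsets[mains[k]] + stats::runif(1, 0.5, 2) * 3600 +
          (j - 1) * 3600
        gs <- round((gs - t0n) / temp_step) * temp_step + t0n
        glen <- sample(seq(600, 1200, by = temp_step), 1L)
        ge <- min(gs + glen, t0n + total_s)
        idx <- which(tt >= gs & tt < ge)
        if (!length(idx)) next
        y[idx] <- shower_temp
        gaps <- rbind(gaps, data.frame(
          start = as.POSIXct(gs, origin = "1970-01-01", tz = .tz),
          end = as.POSIXct(ge, origin = "1970-01-01", tz = .tz)))
      }
    }
  }
  list(series = temperature_series(t0, temp_step, y), shower_gaps = gaps)
}

# --- accelerometry --------------------------------------------------------

simulate_accel <- function(config, truth, t0, t0n, total_s, rate,
                           sensor_noise = 0.003, wake_jitter = 0.05,
                           burst_amp = 0.3) {
  n <- round(total_s * rate)
  tt <- t0n + (seq_len(n) - 1) / rate
  asleep <- in_any_interval(tt, truth$onsets, truth$offsets)

  x <- stats::rnorm(n, 0, sensor_noise)
  yv <- stats::rnorm(n, 0, sensor_noise)
  z <- 1 + stats::rnorm(n, 0, sensor_noise)

  # wake: continuous postural jitter + intermittent movement bursts
  nw <- sum(!asleep)
  if (nw) {
    jit <- function() stats::rnorm(nw, 0, wake_jitter)
    x[!asleep] <- x[!asleep] + jit()
    yv[!asleep] <- yv[!asleep] + jit()
    z[!asleep] <- z[!asleep] + jit()
  }
  add_bursts <- function(idx_pool, rate_per_min, amp, dur_s = c(1, 3)) {
    if (!length(idx_pool)) return(invisible())
    n_b <- stats::rpois(1, rate_per_min * length(idx_pool) / rate / 60)
    if (!n_b) return(invisible())
    starts <- sort(sample(idx_pool, min(n_b, length(idx_pool))))
    for (s0 in starts) {
      len <- max(1L, round(stats::runif(1, dur_s[1], dur_s[2]) * rate))
      ii <- s0:min(s0 + len - 1L, n)
      ii <- ii[!asleep[ii]]  # wake bursts never bleed into sleep
      if (!length(ii)) next
      x[ii] <<- x[ii] + stats::rnorm(length(ii), 0, amp)
      yv[ii] <<- yv[ii] + stats::rnorm(length(ii), 0, amp)
      z[ii] <<- z[ii] + stats::rnorm(length(ii), 0, amp)
    }
  }
  add_bursts(which(!asleep), rate_per_min = 2, amp = burst_amp)

  # phenotype-specific in-sleep movement
  if (nrow(truth$movement)) {
    if (config$movement_mode == "periodic_30s") {
      for (k in seq_len(nrow(truth$movement))) {
        bt <- seq(truth$movement$start[k], truth$movement$end[k], by = 30)
        for (b in bt) {
          ii <- which(tt >= b & tt < b + 2)
          if (!length(ii)) next
          x[ii] <- x[ii] + stats::rnorm(length(ii), 0, burst_amp)
          yv[ii] <- yv[ii] + stats::rnorm(length(ii), 0, burst_amp)
          z[ii] <- z[ii] + stats::rnorm(length(ii), 0, burst_amp)
        }
      }
    } else {
      in_bout <- in_any_interval(tt, truth$movement$start,
                                 truth$movement$end)
      nb <- sum(in_bout)
      if (nb) {
        x[in_bout] <- x[in_bout] + stats::rnorm(nb, 0, 2 * wake_jitter)
        yv[in_bout] <- yv[in_bout] + stats::rnorm(nb, 0, 2 * wake_jitter)
        z[in_bout] <- z[in_bout] + stats::rnorm(nb, 0, 2 * wake_jitter)
      }
    }
  }
  accel_series(t0, rate, cbind(x, yv, z))
}

# --- journal and observation sheet ---------------------------------------

simulate_journal <- function(config, truth, t0n, recall_sd = 300,
                             round_to = 300) {
  mains <- which(truth$kinds == "main")
  on <- truth$onsets[mains]; off <- truth$offsets[mains]
  jon <- round((on + stats::rnorm(length(on), 0, recall_sd)) / round_to) *
    round_to
  joff <- round((off + stats::rnorm(length(off), 0, recall_sd)) / round_to) *
    round_to
  joff <- pmax(joff, jon + round_to)
  nw <- vapply(truth$night[mains], function(k)
    sum(truth$movement$night == k), integer(1))
  sleep_journal(
    date = anchored_date(as.POSIXct(on, origin = "1970-01-01", tz = .tz)),
    onset = as.POSIXct(jon, origin = "1970-01-01", tz = .tz),
    offset = as.POSIXct(joff, origin = "1970-01-01", tz = .tz),
    n_wakes = nw,
    quality = sample(1:5, length(on), replace = TRUE),
    source = "self_report")
}

simulate_sheet <- function(config, truth, t0n, total_s) {
  slot_start <- seq(t0n, t0n + total_s - 1800, by = 1800)
  mid <- slot_start + 900
  sleeping <- in_any_interval(mid, truth$onsets, truth$offsets)
  state <- ifelse(sleeping, "sleeping", "awake")
  missing <- stats::rbinom(length(state), 1,
                           1 - config$sheet_fill_fraction) == 1
  state[missing] <- "missing"
  observation_sheet(as.POSIXct(slot_start, origin = "1970-01-01", tz = .tz),
                    state)
}
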