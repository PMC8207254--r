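# Temperature cleaning, smoothing, segmentation and rhythm indices.

test_that("cleaning replaces sub-floor values by the nearest retained value", {
  # equidistant tie goes to the earlier neighbour
  s <- mk_series(c(34.0, 27.5, 34.4), cleaned = FALSE)
  expect_equal(clean_temperature(s)$values, c(34.0, 34.0, 34.4))
  # leading run takes the first valid point
  s2 <- mk_series(c(25.0, 25.0, 33.1, 33.5), cleaned = FALSE)
  expect_equal(clean_temperature(s2)$values, c(33.1, 33.1, 33.1, 33.5))
  # trailing run takes the last valid point
  s3 <- mk_series(c(33.1, 27.0, 26.0), cleaned = FALSE)
  expect_equal(clean_temperature(s3)$values, c(33.1, 33.1, 33.1))
  # all-clean input is identical; exactly 28.0 is retained
  s4 <- mk_series(c(28.0, 34.0, 30.0), cleaned = FALSE)
  expect_equal(clean_temperature(s4)$values, s4$values)
  expect_true(clean_temperature(s4)$cleaned)
  # unrecoverable: everything below floor
  expect_error(clean_temperature(mk_series(c(25, 26), cleaned = FALSE)),
               "unrecoverable")
})

test_that("cleaning tie-breaks and distances agree with a direct search", {
  set.seed(41)
  for (rep in 1:20) {
    x <- runif(50, 26, 36)
    got <- clean_temperature(mk_series(x, cleaned = FALSE))$values
    want <- x
    valid <- which(x >= 28)
    for (i in which(x < 28)) {
      d <- abs(valid - i)
      want[i] <- x[valid[which.min(d)]]  # which.min takes the earlier tie
    }
    expect_equal(got, want)
  }
})

test_that("median smoothing removes single spikes and keeps endpoints", {
  s <- mk_series(c(33, 40, 33, 33))
  expect_equal(median_smooth(s)$values, c(33, 33, 33, 33))
  # constant and monotone series pass through unchanged
  expect_equal(median_smooth(mk_series(rep(30, 10)))$values, rep(30, 10))
  set.seed(7)
  mono <- sort(runif(40, 28, 36))
  expect_equal(median_smooth(mk_series(mono))$values, mono)
  expect_error(median_smooth(mk_series(c(30, 31)), window = 5), "larger")
  expect_error(median_smooth(mk_series(1:10 + 30), window = 4), "odd")
  expect_error(median_smooth(mk_series(c(30, 31), cleaned = FALSE)),
               "clean")
})

test_that("clean -> smooth -> clean is idempotent on its own output", {
  set.seed(11)
  x <- runif(500, 27, 36)
  out <- median_smooth(clean_temperature(mk_series(x, cleaned = FALSE)))
  again <- clean_temperature(out)
  expect_equal(again$values, out$values)
  expect_equal(median_smooth(again)$values,
               median_smooth(out)$values)
})

test_that("3 PM-anchored segmentation counts 288 samples per complete day", {
  s <- mk_series(rnorm(2 * 288, 33, 0.5))
  seg <- segment_days(s)
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$complete))
  expect_true(all(seg$n_samples == 288))
  expect_true(all(format(seg$window_start, "%H:%M") == "15:00"))

  # a recording from 10:00 to 10:00 intersects two windows, both incomplete
  s2 <- temperature_series(clk("10:00"), 300, rnorm(288, 33), cleaned = TRUE)
  seg2 <- segment_days(s2)
  expect_equal(nrow(seg2), 2L)
  expect_true(all(!seg2$complete))
  expect_equal(sum(seg2$n_samples), 288L)

  # a 14-day wear period yields 14 complete segments
  s3 <- mk_series(rnorm(14 * 288, 33, 0.5))
  expect_equal(sum(segment_days(s3)$complete), 14L)
})

test_that("sleep/wake means split piecewise-constant temperature exactly", {
  n <- 288
  tt <- as.numeric(t15()) + (seq_len(n) - 1) * 300
  sl <- sleep_intervals(clk("23:00"), clk("07:00", add_days = 1))
  asleep <- tt >= as.numeric(sl$onset) & tt < as.numeric(sl$offset)
  s <- mk_series(ifelse(asleep, 35.0, 33.0))
  sw <- sleep_wake_means(s, sl)
  expect_equal(sw$mean_sleep_temp, 35.0)
  expect_equal(sw$mean_wake_temp, 33.0)
  expect_equal(sw$sleep_wake_diff, 2.0)
  expect_equal(sw$n_sleep + sw$n_wake, n)

  expect_error(sleep_wake_means(s, sleep_intervals(NULL, NULL)), "no sleep")
  # intervals covering everything leave no wake samples
  all_sl <- sleep_intervals(t15() - 3600, t15() + 2 * 86400)
  expect_error(sleep_wake_means(s, all_sl), "outside")
})

test_that("IS is 1 for exactly 24-h-periodic signals and errors on 0/0", {
  set.seed(21)
  template <- rnorm(288, 33, 1)
  s <- mk_series(rep(template, 4))
  expect_equal(interday_stability(s), 1.0, tolerance = 1e-9)
  # at full resolution too
  expect_equal(interday_stability(s, bin_width = 300), 1.0,
               tolerance = 1e-9)
  expect_error(interday_stability(mk_series(rep(33, 2 * 288))), "undefined")
  expect_error(interday_stability(mk_series(rnorm(288))), "2 complete")
})

test_that("IV matches closed forms: alternating sequence 4, cosine (2*pi/24)^2", {
  # hourly sampling, hourly bins: binning is the identity
  alt <- mk_series(rep(c(1, -1), 24), step = 3600)
  expect_equal(intraday_variability(alt), 4.0)
  cosine <- mk_cosinor_series(33, 1, 246, n_days = 30, step = 3600)
  # exact discrete value 4*sin(pi/24)^2, approaching (2*pi/24)^2 as the
  # step shrinks
  expect_equal(intraday_variability(cosine), 4 * sin(pi / 24)^2,
               tolerance = 5e-3)
  expect_equal(intraday_variability(cosine), (2 * pi / 24)^2,
               tolerance = 1e-2)
  expect_error(intraday_variability(mk_series(rep(33, 288))), "undefined")
})

test_that("IS and IV are invariant to affine rescaling of the series", {
  set.seed(31)
  s <- mk_cosinor_series(33, 1.5, 240, n_days = 4, noise_sd = 0.4)
  s2 <- mk_series(3 + 2.5 * s$values)
  expect_equal(interday_stability(s2), interday_stability(s),
               tolerance = 1e-12)
  expect_equal(intraday_variability(s2), intraday_variability(s),
               tolerance = 1e-12)
})

test_that("shuffling samples within days degrades IS below the periodic ideal", {
  set.seed(51)
  template <- 33 + 2 * sin(seq(0, 2 * pi, length.out = 289))[-289] +
    rnorm(288, 0, 0.2)
  ident <- mk_series(rep(template, 4))
  shuffled <- mk_series(as.vector(vapply(1:4, function(i) sample(template),
                                         numeric(288))))
  expect_lt(interday_stability(shuffled), interday_stability(ident))
})

test_that("vectorized IS/IV equal a literal formula transcription", {
  set.seed(61)
  for (rep in 1:25) {
    n_days <- sample(2:4, 1)
    step <- sample(c(600, 1200, 3600), 1)
    bw <- sample(c(3600, 7200), 1)
    s <- mk_series(rnorm(n_days * 86400 / step, 33, 1), step = step)
    tt <- series_times(s)
    expect_equal(interday_stability(s, bw), is_oracle(s$values, tt, bw),
                 tolerance = 1e-12)
    expect_equal(intraday_variability(s, bw), iv_oracle(s$values, tt, bw),
                 tolerance = 1e-12)
  }
})

test_that("cosinor recovers noiseless parameters to numerical precision", {
  s <- mk_cosinor_series(33.34, 1.72, 246, n_days = 3)
  cf <- cosinor_fit(s)
  expect_equal(cf$mesor, 33.34, tolerance = 1e-6)
  expect_equal(cf$amplitude, 1.72, tolerance = 1e-6)
  expect_equal(cf$acrophase_min, 246, tolerance = 1e-6)
  expect_lt(cf$residual_sd, 1e-8)

  flat <- cosinor_fit(mk_series(rep(33.5, 288)))
  expect_equal(flat$mesor, 33.5)
  expect_equal(flat$amplitude, 0, tolerance = 1e-12)
  expect_true(is.na(flat$acrophase_min))
})

test_that("cosinor is equivariant under time shifts and level shifts", {
  s <- mk_cosinor_series(33.9, 0.93, 44, n_days = 2)
  base <- cosinor_fit(s)
  for (shift_min in c(35, 250, 710)) {
    shifted <- temperature_series(s$start + shift_min * 60, s$step,
                                  s$values, cleaned = TRUE)
    cf <- cosinor_fit(shifted)
    expect_equal(cf$acrophase_min,
                 (base$acrophase_min + shift_min) %% 1440,
                 tolerance = 1e-6)
    expect_equal(cf$amplitude, base$amplitude, tolerance = 1e-6)
  }
  up <- temperature_series(s$start, s$step, s$values + 2.5, cleaned = TRUE)
  cf <- cosinor_fit(up)
  expect_equal(cf$mesor, base$mesor + 2.5, tolerance = 1e-9)
  expect_equal(cf$amplitude, base$amplitude, tolerance = 1e-9)
  expect_equal(cf$acrophase_min, base$acrophase_min, tolerance = 1e-6)
})

test_that("rhythm_summary runs the full temperature pipeline on raw input", {
  set.seed(71)
  sub <- generate_subject(phenotype_config("regular_young"), n_days = 3,
                          seed = 14, accel_rate = 0.1)
  r <- rhythm_summary(sub$temperature, sub$truth$sleep_intervals)
  expect_equal(nrow(r), 1L)
  expect_true(all(is.finite(unlist(r))))
  expect_equal(r$sleep_wake_diff, r$mean_sleep_temp - r$mean_wake_temp)
  expect_gte(r$is_value, 0); expect_lte(r$is_value, 1 + 1e-9)
  expect_gte(r$iv_value, 0)
  expect_equal(r$n_complete_days, 3L)
})
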