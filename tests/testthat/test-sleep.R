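# Epoching, sleep-period identification, journal recreation, and the
# motion-only surrogate detector.

test_that("a still wrist scores zero activity; bursts stay local", {
  acc <- mk_still_accel(2)
  prof <- epoch_activity(acc)
  expect_equal(nrow(prof), 240L)
  expect_true(all(prof$activity == 0))
  expect_true(all(prof$static))

  # one 10-s burst in epoch 5 only
  mv <- data.frame(start = t15() + 4 * 30 + 10, end = t15() + 4 * 30 + 20)
  set.seed(3)
  acc2 <- mk_still_accel(2, move = mv)
  prof2 <- epoch_activity(acc2)
  expect_false(prof2$static[5])
  expect_true(all(prof2$static[-5]))

  expect_error(epoch_activity(mk_still_accel(2), epoch_length = 7.3),
               "whole|at least")
})

test_that("identification recovers a quiet night within one epoch", {
  set.seed(5)
  sub <- generate_subject(phenotype_config("regular_young",
                                           shower_rate = 0),
                          n_days = 2, seed = 51, accel_rate = 1)
  prof <- epoch_activity(sub$accel)
  seg <- segment_days(clean_temperature(sub$temperature))
  seg <- seg[seg$complete, ]
  truth <- sub$truth$sleep_intervals
  for (k in seq_len(nrow(seg))) {
    iv <- identify_sleep_periods(prof, seg$window_start[k],
                                 seg$window_end[k])
    main <- iv[iv$kind == "main", ]
    expect_equal(nrow(main), 1L)
    expect_lte(abs(as.numeric(main$onset) - as.numeric(truth$onset[k])), 30)
    expect_lte(abs(as.numeric(main$offset) - as.numeric(truth$offset[k])),
               30)
    # disjoint and inside the queried window
    expect_true(all(iv$onset >= seg$window_start[k]))
    expect_true(all(iv$offset <= seg$window_end[k]))
    if (nrow(iv) > 1L)
      expect_true(all(head(iv$offset, -1) <= tail(iv$onset, -1)))
  }
})

test_that("a long mid-night wake splits the night and the longer side wins", {
  # static 21:00-01:00, movement 01:00-03:30 (2.5 h), static 03:30-07:00
  set.seed(9)
  mv <- data.frame(start = clk("01:00", add_days = 1),
                   end = clk("03:30", add_days = 1))
  wake1 <- data.frame(start = t15(), end = clk("21:00"))
  wake2 <- data.frame(start = clk("07:00", add_days = 1),
                      end = t15() + 86400)
  acc <- mk_still_accel(24, move = rbind(wake1, mv, wake2))
  prof <- epoch_activity(acc)
  iv <- identify_sleep_periods(prof, t15(), t15() + 86400)
  main <- iv[iv$kind == "main", ]
  expect_equal(nrow(main), 1L)
  expect_equal(format(main$onset, "%H:%M"), "21:00")
  expect_equal(format(main$offset, "%H:%M"), "01:00")
  # the second static block is reported separately, not merged: the 2.5-h
  # wake gap contributes no sleep anywhere
  other <- iv[iv$kind != "main", ]
  expect_equal(nrow(other), 1L)
  expect_equal(other$kind, "nap")
  expect_equal(format(other$onset, "%H:%M"), "03:30")
  expect_equal(sum(iv$sleep_min), 4 * 60 + 3.5 * 60)
})

test_that("short gaps merge but still count as wake in sleep_min", {
  # static 23:00-02:00, movement 02:00-02:05, static 02:05-07:00
  set.seed(13)
  mv <- data.frame(start = clk("02:00", add_days = 1),
                   end = clk("02:05", add_days = 1))
  wake1 <- data.frame(start = t15(), end = clk("23:00"))
  wake2 <- data.frame(start = clk("07:00", add_days = 1),
                      end = t15() + 86400)
  acc <- mk_still_accel(24, move = rbind(wake1, mv, wake2))
  prof <- epoch_activity(acc)
  iv <- identify_sleep_periods(prof, t15(), t15() + 86400)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$kind, "main")
  expect_equal(format(iv$onset, "%H:%M"), "23:00")
  expect_equal(format(iv$offset, "%H:%M"), "07:00")
  expect_equal(iv$sleep_min, 8 * 60 - 5)
})

test_that("fragmented sleepers yield fragments and no main sleep", {
  sub <- generate_subject(phenotype_config("fragmented_oawd",
                                           shower_rate = 0),
                          n_days = 2, seed = 61, accel_rate = 1)
  prof <- epoch_activity(sub$accel)
  seg <- segment_days(clean_temperature(sub$temperature))
  seg <- seg[seg$complete, ]
  for (k in seq_len(nrow(seg))) {
    iv <- identify_sleep_periods(prof, seg$window_start[k],
                                 seg$window_end[k])
    expect_gt(nrow(iv), 0L)
    expect_true(all(iv$kind == "fragment"))
  }
})

test_that("no static epochs means no sleep intervals", {
  set.seed(17)
  mv <- data.frame(start = t15(), end = t15() + 4 * 3600)
  acc <- mk_still_accel(4, move = mv)
  prof <- epoch_activity(acc)
  expect_equal(nrow(identify_sleep_periods(prof, t15(), t15() + 4 * 3600)),
               0L)
})

test_that("recreated journals honour sheet precedence", {
  # a fully filled sheet is copied verbatim, accelerometry ignored
  slots <- seq(t15(), t15() + 86400 - 1800, by = 1800)
  truth_sleep <- slots >= clk("23:00") & slots < clk("07:00", add_days = 1)
  sheet <- observation_sheet(slots,
                             ifelse(truth_sleep, "sleeping", "awake"))
  contradicting <- sleep_intervals(clk("20:00"), clk("22:00"))
  j <- recreate_journal(contradicting, sheet)
  expect_equal(nrow(j), 1L)
  expect_equal(format(j$onset, "%H:%M"), "23:00")
  expect_equal(format(j$offset, "%H:%M"), "07:00")

  # an observed awake slot beats static accelerometry
  st <- ifelse(truth_sleep, "sleeping", "awake")
  st[slots == clk("01:00", add_days = 1)] <- "awake"
  j2 <- recreate_journal(sleep_intervals(clk("23:00"),
                                         clk("07:00", add_days = 1)),
                         observation_sheet(slots, st))
  # the 01:00 awake slot splits the night; the longest run is reported
  expect_equal(j2$n_wakes, 1L)
  expect_equal(format(j2$onset, "%H:%M"), "01:30")

  # missing slots are filled from the intervals
  st2 <- ifelse(truth_sleep, "sleeping", "awake")
  st2[seq(1, length(st2), by = 2)] <- "missing"
  j3 <- recreate_journal(sleep_intervals(clk("23:00"),
                                         clk("07:00", add_days = 1)),
                         observation_sheet(slots, st2))
  expect_equal(format(j3$onset, "%H:%M"), "23:00")
  expect_equal(format(j3$offset, "%H:%M"), "07:00")

  # flipping one filled slot never changes accel-filled slots: with the
  # 00:00 slot flipped to awake, only that slot's contribution moves
  st3 <- st2
  st3[slots == clk("00:00", add_days = 1)] <- "awake"
  j4 <- recreate_journal(sleep_intervals(clk("23:00"),
                                         clk("07:00", add_days = 1)),
                         observation_sheet(slots, st3))
  expect_equal(format(j4$offset, "%H:%M"), format(j3$offset, "%H:%M"))

  # fully missing sheet + no intervals -> empty journal
  j5 <- recreate_journal(sleep_intervals(NULL, NULL),
                         observation_sheet(slots, rep("missing",
                                                      length(slots))))
  expect_equal(nrow(j5), 0L)
})

test_that("fragment-only evidence is flagged low-confidence", {
  slots <- seq(t15(), t15() + 86400 - 1800, by = 1800)
  sheet <- observation_sheet(slots, rep("missing", length(slots)))
  frags <- sleep_intervals(
    c(clk("23:00"), clk("00:30", add_days = 1)),
    c(clk("23:25", add_days = 0), clk("00:55", add_days = 1)),
    kind = "fragment")
  j <- recreate_journal(frags, sheet)
  expect_true(all(j$low_confidence))
})

test_that("the surrogate detector reports quiet nights and misses fragmented ones", {
  quiet <- generate_subject(phenotype_config("regular_young",
                                             shower_rate = 0),
                            n_days = 3, seed = 71, accel_rate = 1)
  frag <- generate_subject(phenotype_config("fragmented_oawd",
                                            shower_rate = 0),
                           n_days = 3, seed = 72, accel_rate = 1)
  for (sub in list(quiet, frag)) {
    prof <- epoch_activity(sub$accel)
    seg <- segment_days(clean_temperature(sub$temperature))
    seg <- seg[seg$complete, ]
    n_valid <- 0L
    for (k in seq_len(nrow(seg))) {
      dj <- surrogate_device_detect(prof, seg$window_start[k],
                                    seg$window_end[k])
      n_valid <- n_valid + (nrow(dj) > 0L)
    }
    if (identical(sub, quiet)) expect_equal(n_valid, 3L)
    else expect_equal(n_valid, 0L)
  }
})

test_that("periodic in-sleep movement delays the surrogate onset by the window", {
  sub <- generate_subject(phenotype_config("regular_old", shower_rate = 0),
                          n_days = 3, seed = 81, accel_rate = 1)
  prof <- epoch_activity(sub$accel)
  seg <- segment_days(clean_temperature(sub$temperature))
  seg <- seg[seg$complete, ]
  truth <- sub$truth$sleep_intervals
  for (k in seq_len(nrow(seg))) {
    dj <- surrogate_device_detect(prof, seg$window_start[k],
                                  seg$window_end[k])
    expect_equal(nrow(dj), 1L)
    delay_min <- (as.numeric(dj$onset) - as.numeric(truth$onset[k])) / 60
    expect_gte(delay_min, 2.5 * 60)
  }
})

test_that("adding in-sleep movement never increases surrogate-valid days", {
  # movement density rises from quiet to periodic to fragmented; the count
  # of days with device-reported sleep must be non-increasing
  counts <- vapply(c("quiet", "periodic_30s", "fragmented"), function(mode) {
    cfg <- phenotype_config("regular_old", movement_mode = mode,
                            shower_rate = 0)
    sub <- generate_subject(cfg, n_days = 3, seed = 91, accel_rate = 1)
    prof <- epoch_activity(sub$accel)
    seg <- segment_days(clean_temperature(sub$temperature))
    seg <- seg[seg$complete, ]
    sum(vapply(seq_len(nrow(seg)), function(k)
      nrow(surrogate_device_detect(prof, seg$window_start[k],
                                   seg$window_end[k])) > 0L, logical(1)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
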