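#' Epoch-level activity profile from raw accelerometry
#'
#' Summarises raw tri-axial accelerometry into fixed-length epochs: per
#' epoch, the activity score is the standard deviation of the vector
#' magnitude `sqrt(x^2 + y^2 + z^2)` within the epoch (gravity cancels out of
#' the SD, so a motionless wrist scores near 0 regardless of orientation).
#' Epochs scoring below `static_threshold` are flagged static.
#'
#' @param accel an [accel_series()].
#' @param epoch_length epoch length in seconds (default 30).
#' @param static_threshold activity below which an epoch counts as static, in
#'   g (default 0.02).
#'
#' @return data.frame of class `activity_profile`: `epoch_start` (POSIXct),
#'   `activity` (g), `static` (logical); attribute `epoch_length`.
#' @export
epoch_activity <- function(accel, epoch_length = 30,
                           static_threshold = 0.02) {
  stopifnot(inherits(accel, "accel_series"))
  per_epoch <- epoch_length * accel$rate
  if (abs(per_epoch - round(per_epoch)) > 1e-9 || per_epoch < 2)
    stop("`epoch_length` must hold at least 2 whole samples", call. = FALSE)
  per_epoch <- round(per_epoch)
  n <- nrow(accel$values)
  n_epochs <- n %/% per_epoch
  if (n_epochs < 1L)
    stop("recording shorter than one epoch", call. = FALSE)
  vm <- sqrt(rowSums(accel$values^2))
  vm <- vm[seq_len(n_epochs * per_epoch)]
  grp <- rep(seq_len(n_epochs), each = per_epoch)
  act <- vapply(split(vm, grp), stats::sd, numeric(1))
  out <- data.frame(
    epoch_start = accel$start + (seq_len(n_epochs) - 1L) * epoch_length,
    activity = unname(act),
    static = unname(act) < static_threshold)
  attr(out, "epoch_length") <- epoch_length
  attr(out, "static_threshold") <- static_threshold
  class(out) <- c("activity_profile", "data.frame")
  out
}

# maximal runs of static epochs inside an index range; returns a data.frame
# of epoch-index ranges (inclusive)
static_runs <- function(static, from, to) {
  if (from > to) return(data.frame(first = integer(0), last = integer(0)))
  r <- rle(static[from:to])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(first = from - 1L + starts[keep], last = from - 1L + ends[keep])
}

#' Identify sleep periods within one 3 PM-anchored day
#'
#' Algorithmic version of manual sleep scoring from raw actigraphy: sleep
#' shows as long runs of near-static epochs. Maximal static runs within the
#' day window are formed; runs separated by non-static gaps shorter than
#' `merge_tolerance` are merged into one candidate period (the gap still
#' counts as wake, not sleep, towards the period's `sleep_min`). An internal
#' wake gap longer than `max_wake_gap` (default 2 h) splits a candidate and
#' only the pieces survive. The main sleep is the longest candidate (ties:
#' lower mean activity, then earlier start), provided it reaches
#' `min_main_sleep`; remaining candidates of at least `min_nap` become naps,
#' and shorter ones interleaved with movement are labelled fragments. With
#' only sub-30-min static episodes (fragmented sleepers) no main sleep is
#' reported.
#'
#' @param profile an [epoch_activity()] profile covering the day.
#' @param window_start,window_end POSIXct bounds of the 3 PM-anchored day
#'   (e.g. one row of [segment_days()]).
#' @param merge_tolerance maximal non-static gap (seconds) bridged when
#'   merging runs. Default 600 (10 min).
#' @param max_wake_gap internal wake gap (seconds) above which a candidate is
#'   split. Default 7200 (2 h).
#' @param min_main_sleep minimum main-sleep span in seconds. Default 10800
#'   (3 h).
#' @param min_nap minimum nap span in seconds. Default 1200 (20 min).
#'
#' @return a [sleep_intervals()] table (possibly empty); `sleep_min` counts
#'   static time only, excluding merged wake gaps.
#' @export
identify_sleep_periods <- function(profile, window_start, window_end,
                                   merge_tolerance = 600,
                                   max_wake_gap = 7200,
                                   min_main_sleep = 10800,
                                   min_nap = 1200) {
  stopifnot(inherits(profile, "activity_profile"))
  el <- attr(profile, "epoch_length")
  t_ep <- as.numeric(profile$epoch_start)
  in_day <- which(t_ep >= as.numeric(window_start) &
                    t_ep + el <= as.numeric(window_end))
  if (!length(in_day)) return(sleep_intervals(NULL, NULL))
  runs <- static_runs(profile$static, in_day[1L], in_day[length(in_day)])
  if (!nrow(runs)) return(sleep_intervals(NULL, NULL))

  # merge runs across short non-static gaps
  merged <- list()
  cur <- c(runs$first[1L], runs$last[1L])
  members <- list(1L)
  cur_members <- 1L
  if (nrow(runs) > 1L) {
    for (k in 2L:nrow(runs)) {
      gap <- (runs$first[k] - cur[2L] - 1L) * el
      if (gap < merge_tolerance) {
        cur[2L] <- runs$last[k]
        cur_members <- c(cur_members, k)
      } else {
        merged[[length(merged) + 1L]] <- cur
        members[[length(members)]] <- cur_members
        cur <- c(runs$first[k], runs$last[k])
        cur_members <- k
        members[[length(members) + 1L]] <- cur_members
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur
  members[[length(members)]] <- cur_members

  # split candidates at internal wake gaps longer than max_wake_gap
  pieces <- list()
  for (m in seq_along(merged)) {
    ks <- members[[m]]
    piece <- runs$first[ks[1L]]
    piece_runs <- ks[1L]
    if (length(ks) > 1L) {
      for (j in 2L:length(ks)) {
        gap <- (runs$first[ks[j]] - runs$last[ks[j - 1L]] - 1L) * el
        if (gap > max_wake_gap) {
          pieces[[length(pieces) + 1L]] <-
            list(first = piece, last = runs$last[ks[j - 1L]],
                 runs = piece_runs)
          piece <- runs$first[ks[j]]
          piece_runs <- ks[j]
        } else piece_runs <- c(piece_runs, ks[j])
      }
    }
    pieces[[length(pieces) + 1L]] <-
      list(first = piece, last = runs$last[ks[length(ks)]], runs = piece_runs)
  }

  span_s <- vapply(pieces, function(p) (p$last - p$first + 1L) * el,
                   numeric(1))
  static_s <- vapply(pieces, function(p)
    sum((runs$last[p$runs] - runs$first[p$runs] + 1L)) * el, numeric(1))
  mean_act <- vapply(pieces, function(p) {
    idx <- unlist(Map(seq, runs$first[p$runs], runs$last[p$runs]))
    mean(profile$activity[idx])
  }, numeric(1))

  # main sleep: longest span; ties -> least varied (lower mean activity),
  # then earlier
  main_idx <- NA_integer_
  qualifying <- which(span_s >= min_main_sleep)
  if (length(qualifying)) {
    o <- qualifying[order(-span_s[qualifying], mean_act[qualifying],
                          vapply(pieces[qualifying], `[[`, numeric(1),
                                 "first"))]
    main_idx <- o[1L]
  }
  # without a qualifying main sleep the day's evidence is fragmentary:
  # short static episodes interleaved with movement, not naps
  kind <- rep("fragment", length(pieces))
  if (!is.na(main_idx)) {
    kind[span_s >= min_nap] <- "nap"
    kind[main_idx] <- "main"
  }
  onset <- profile$epoch_start[vapply(pieces, `[[`, numeric(1), "first")]
  offset <- profile$epoch_start[vapply(pieces, `[[`, numeric(1), "last")] + el
  sleep_intervals(onset, offset, kind = kind, mean_activity = mean_act,
                  sleep_min = static_s / 60)
}

#' Recreate a nightly sleep journal from sheets and actigraphy
#'
#' Combines a partially completed caregiver observation sheet with
#' accelerometry-identified sleep intervals into one journal. Observed slots
#' (awake/sleeping) always win; only missing slots are filled from the
#' identified intervals (a slot counts as sleeping when its midpoint falls in
#' a main or nap interval). The resulting half-hour state sequence is reduced
#' to one nightly onset/offset per 3 PM-anchored day: the longest sleeping
#' run of the night, extended across single awake interruptions is not
#' attempted — runs are taken literally, and the number of extra sleeping
#' runs in the same night is reported as `n_wakes`. Nights whose sleep
#' evidence comes only from fragment intervals are flagged low-confidence.
#'
#' @param intervals a [sleep_intervals()] table from
#'   [identify_sleep_periods()].
#' @param sheet an [observation_sheet()].
#'
#' @return a [sleep_journal()] with source `"recreated"`.
#' @export
recreate_journal <- function(intervals, sheet) {
  stopifnot(inherits(sheet, "observation_sheet"))
  slots <- sheet$slot_start
  state <- sheet$state
  mid <- as.numeric(slots) + 900

  filled_from <- rep("sheet", length(slots))
  miss <- state == "missing"
  if (any(miss)) {
    solid <- intervals[intervals$kind %in% c("main", "nap"), , drop = FALSE]
    frag <- intervals[intervals$kind == "fragment", , drop = FALSE]
    in_solid <- in_any_interval(mid[miss], as.numeric(solid$onset),
                                as.numeric(solid$offset))
    in_frag <- in_any_interval(mid[miss], as.numeric(frag$onset),
                               as.numeric(frag$offset))
    state[miss] <- ifelse(in_solid | in_frag, "sleeping", "awake")
    filled_from[miss] <- ifelse(in_frag & !in_solid, "accel_fragment",
                                "accel")
  }
  if (all(state == "missing") || !length(slots))
    return(sleep_journal(NULL, NULL, NULL, source = "recreated"))

  day <- anchored_date(slots)
  rows <- lapply(split(seq_along(slots), day), function(idx) {
    sl <- state[idx] == "sleeping"
    if (!any(sl)) return(NULL)
    r <- rle(sl)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sruns <- which(r$values)
    lens <- r$lengths[sruns]
    best <- sruns[which.max(lens)]
    i0 <- idx[starts[best]]; i1 <- idx[ends[best]]
    lc <- all(filled_from[idx][sl] %in% c("accel_fragment")) &&
      any(filled_from[idx][sl] == "accel_fragment")
    data.frame(date = day[idx[1L]],
               onset = slots[i0],
               offset = slots[i1] + 1800,
               n_wakes = length(sruns) - 1L,
               low_confidence = lc)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || !nrow(rows))
    return(sleep_journal(NULL, NULL, NULL, source = "recreated"))
  sleep_journal(rows$date, rows$onset, rows$offset, n_wakes = rows$n_wakes,
                source = "recreated", low_confidence = rows$low_confidence)
}

#' Motion-only surrogate sleep detector
#'
#' A deliberately motion-biased stand-in for commercial wristband sleep
#' detection (whose algorithms are proprietary): it opens a sleep period only
#' after `open_after` consecutive static epochs, closes it after
#' `close_after` consecutive non-static epochs, and reports at most the
#' single longest such period per 3 PM-anchored day — or no sleep at all when
#' none qualifies. By construction it reproduces the failure modes of
#' movement-based detection: onsets are delayed past periodic in-sleep
#' movement, and fragmented sleepers (no static run long enough to open a
#' period) get no sleep reported. It is a research surrogate, not a
#' reverse-engineering of any commercial algorithm.
#'
#' @param profile an [epoch_activity()] profile.
#' @param window_start,window_end POSIXct bounds of the 3 PM-anchored day.
#' @param open_after consecutive static epochs required to open a sleep
#'   period (default 120, i.e. 60 min at 30-s epochs).
#' @param close_after consecutive non-static epochs that close it
#'   (default 10).
#'
#' @return a [sleep_journal()] with source `"device"`; zero rows when no
#'   period qualifies.
#' @export
surrogate_device_detect <- function(profile, window_start, window_end,
                                    open_after = 120L, close_after = 10L) {
  stopifnot(inherits(profile, "activity_profile"))
  el <- attr(profile, "epoch_length")
  t_ep <- as.numeric(profile$epoch_start)
  in_day <- which(t_ep >= as.numeric(window_start) &
                    t_ep + el <= as.numeric(window_end))
  empty <- sleep_journal(NULL, NULL, NULL, source = "device")
  if (!length(in_day)) return(empty)
  s <- profile$static[in_day]

  periods <- list()
  i <- 1L; n <- length(s)
  while (i <= n) {
    # find open_after consecutive static epochs
    run <- 0L; start <- NA_integer_
    while (i <= n) {
      if (s[i]) {
        if (run == 0L) start <- i
        run <- run + 1L
        if (run >= open_after) break
      } else run <- 0L
      i <- i + 1L
    }
    if (i > n || run < open_after) break
    # period is open; close after close_after consecutive non-static epochs
    bad <- 0L; last_static <- i
    while (i <= n) {
      if (s[i]) { bad <- 0L; last_static <- i } else {
        bad <- bad + 1L
        if (bad >= close_after) break
      }
      i <- i + 1L
    }
    periods[[length(periods) + 1L]] <- c(start, last_static)
    i <- i + 1L
  }
  if (!length(periods)) return(empty)
  lens <- vapply(periods, function(p) p[2L] - p[1L] + 1L, integer(1))
  best <- periods[[which.max(lens)]]
  onset <- profile$epoch_start[in_day[best[1L]]]
  offset <- profile$epoch_start[in_day[best[2L]]] + el
  sleep_journal(anchored_date(window_start + 1), onset, offset,
                source = "device")
}
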