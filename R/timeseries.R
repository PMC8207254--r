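#' Uniformly sampled wrist-temperature series
#'
#' Container for a wrist (distal skin) temperature recording sampled on a
#' uniform grid: sample `i` (1-based) is taken at `start + (i - 1) * step`.
#' Distal skin temperature is the substrate of all rhythm statistics in this
#' package: it rises before and during sleep as the body dissipates heat, and
#' falls after waking, mirroring core body temperature in antiphase.
#'
#' @param start `POSIXct` timestamp of the first sample (fixed-offset local
#'   clock; no DST).
#' @param step sampling interval in seconds (default 300, i.e. 5 min).
#' @param values numeric vector of temperatures in degrees Celsius.
#' @param cleaned logical; `TRUE` once non-wear values (below the skin-contact
#'   floor) have been replaced by [clean_temperature()].
#'
#' @return An object of class `temperature_series`.
#' @seealso [clean_temperature()], [median_smooth()], [segment_days()]
#' @export
#' @examples
#' t0 <- as.POSIXct("2024-01-01 15:00:00", tz = "UTC")
#' ts <- temperature_series(t0, 300, 33 + sin(seq(0, 4 * pi, length.out = 576)))
#' ts
temperature_series <- function(start, step = 300, values, cleaned = FALSE) {
  stopifnot(inherits(start, "POSIXct"), length(start) == 1L)
  step <- as.numeric(step)
  if (!is.finite(step) || step <= 0)
    stop("`step` must be a positive number of seconds", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("`values` must be non-empty", call. = FALSE)
  structure(
    list(start = start, step = step, values = values,
         cleaned = isTRUE(cleaned)),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<temperature_series> %d samples @ %gs from %s (%.1f days)%s\n",
    n, x$step, format(x$start, "%Y-%m-%d %H:%M"),
    n * x$step / 86400, if (x$cleaned) ", cleaned" else ""))
  fin <- x$values[is.finite(x$values)]
  if (length(fin))
    cat(sprintf("  range %.2f..%.2f degC\n", min(fin), max(fin)))
  invisible(x)
}

#' @export
length.temperature_series <- function(x) length(x$values)

#' Sample timestamps of a uniform series
#'
#' @param x a [temperature_series()] or [accel_series()].
#' @return `POSIXct` vector, one timestamp per sample.
#' @export
series_times <- function(x) {
  UseMethod("series_times")
}

#' @export
series_times.temperature_series <- function(x) {
  x$start + (seq_along(x$values) - 1L) * x$step
}

#' @export
series_times.accel_series <- function(x) {
  x$start + (seq_len(nrow(x$values)) - 1L) / x$rate
}

#' @export
as.data.frame.temperature_series <- function(x, ...) {
  data.frame(timestamp = series_times(x), temp_c = x$values)
}

#' Tri-axial accelerometry series
#'
#' Raw accelerometer recording in g units, uniformly sampled. Gravity is
#' included, so a motionless wrist reads a constant 1 g vector magnitude
#' (plus sensor noise).
#'
#' @param start `POSIXct` timestamp of the first sample.
#' @param rate sampling rate in samples per second.
#' @param values numeric matrix with three columns (x, y, z) in g.
#'
#' @return An object of class `accel_series`.
#' @seealso [epoch_activity()]
#' @export
accel_series <- function(start, rate, values) {
  stopifnot(inherits(start, "POSIXct"), length(start) == 1L)
  rate <- as.numeric(rate)
  if (!is.finite(rate) || rate <= 0)
    stop("`rate` must be a positive sampling rate (Hz)", call. = FALSE)
  values <- as.matrix(values)
  if (ncol(values) != 3L || nrow(values) == 0L)
    stop("`values` must be a non-empty 3-column (x,y,z) matrix", call. = FALSE)
  colnames(values) <- c("x_g", "y_g", "z_g")
  structure(list(start = start, rate = rate, values = values),
            class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<accel_series> %d samples @ %g Hz from %s (%.1f days)\n",
              n, x$rate, format(x$start, "%Y-%m-%d %H:%M"),
              n / x$rate / 86400))
  invisible(x)
}

#' @export
as.data.frame.accel_series <- function(x, ...) {
  data.frame(timestamp = series_times(x),
             x_g = x$values[, 1L], y_g = x$values[, 2L], z_g = x$values[, 3L])
}

#' Sleep-interval table constructor
#'
#' Builds and validates a table of labelled sleep intervals. Intervals of one
#' subject must be pairwise disjoint and each onset must precede its offset.
#'
#' @param onset,offset `POSIXct` vectors of equal length.
#' @param kind character, each one of `"main"`, `"nap"`, `"fragment"`.
#' @param mean_activity per-interval mean epoch activity in g (`NA` when
#'   unknown, e.g. for self-reported intervals).
#' @param sleep_min minutes actually asleep within the interval (defaults to
#'   the interval length; identified intervals may exclude brief wake gaps).
#'
#' @return data.frame of class `sleep_intervals` with columns `onset`,
#'   `offset`, `kind`, `mean_activity`, `sleep_min`.
#' @export
sleep_intervals <- function(onset, offset, kind = "main",
                            mean_activity = NA_real_, sleep_min = NULL) {
  if (length(onset) == 0L) {
    out <- data.frame(onset = as.POSIXct(character(), tz = .tz),
                      offset = as.POSIXct(character(), tz = .tz),
                      kind = character(), mean_activity = numeric(),
                      sleep_min = numeric())
    class(out) <- c("sleep_intervals", "data.frame")
    return(out)
  }
  stopifnot(inherits(onset, "POSIXct"), inherits(offset, "POSIXct"),
            length(onset) == length(offset))
  kind <- rep_len(as.character(kind), length(onset))
  if (!all(kind %in% c("main", "nap", "fragment")))
    stop("`kind` must be one of 'main', 'nap', 'fragment'", call. = FALSE)
  if (any(!(onset < offset)))
    stop("every sleep interval needs onset < offset", call. = FALSE)
  o <- order(onset)
  onset <- onset[o]; offset <- offset[o]; kind <- kind[o]
  mean_activity <- rep_len(as.numeric(mean_activity), length(onset))[o]
  if (is.null(sleep_min)) sleep_min <- as.numeric(offset - onset, units = "mins")
  else sleep_min <- rep_len(as.numeric(sleep_min), length(onset))[o]
  if (length(onset) > 1L && any(utils::head(offset, -1L) > utils::tail(onset, -1L)))
    stop("sleep intervals of one subject must not overlap", call. = FALSE)
  out <- data.frame(onset = onset, offset = offset, kind = kind,
                    mean_activity = mean_activity, sleep_min = sleep_min)
  class(out) <- c("sleep_intervals", "data.frame")
  out
}

#' Sleep-journal constructor
#'
#' One record per night: the 3 PM-anchored day a night belongs to is the day
#' containing its onset. `source` records provenance: participant self-report,
#' a journal recreated from actigraphy + observation sheets, a device report,
#' or simulator ground truth.
#'
#' @param date `Date` of the 3 PM-anchored day the night belongs to.
#' @param onset,offset `POSIXct` sleep onset and final wake.
#' @param n_wakes integer count of night-time wake-ups (NA if unknown).
#' @param quality subjective quality score 1-5 (NA if unknown).
#' @param source one of `"self_report"`, `"recreated"`, `"device"`,
#'   `"ground_truth"`.
#' @param duration_min minutes of sleep credited to the night; defaults to
#'   `offset - onset`.
#' @param low_confidence logical flag for nights supported only by fragmented
#'   movement evidence.
#'
#' @return data.frame of class `sleep_journal`.
#' @export
sleep_journal <- function(date, onset, offset, n_wakes = NA_integer_,
                          quality = NA_real_, source = "self_report",
                          duration_min = NULL, low_confidence = FALSE) {
  source <- match.arg(source,
                      c("self_report", "recreated", "device", "ground_truth"))
  n <- length(date)
  if (n == 0L) {
    out <- data.frame(date = as.Date(character()),
                      onset = as.POSIXct(character(), tz = .tz),
                      offset = as.POSIXct(character(), tz = .tz),
                      duration_min = numeric(), n_wakes = integer(),
                      quality = numeric(), low_confidence = logical())
  } else {
    stopifnot(inherits(onset, "POSIXct"), inherits(offset, "POSIXct"))
    if (anyDuplicated(date))
      stop("at most one main-sleep entry per 3 PM-anchored day", call. = FALSE)
    if (is.null(duration_min))
      duration_min <- as.numeric(offset - onset, units = "mins")
    out <- data.frame(date = as.Date(date), onset = onset, offset = offset,
                      duration_min = as.numeric(duration_min),
                      n_wakes = rep_len(as.integer(n_wakes), n),
                      quality = rep_len(as.numeric(quality), n),
                      low_confidence = rep_len(as.logical(low_confidence), n))
    out <- out[order(out$date), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "source") <- source
  class(out) <- c("sleep_journal", "data.frame")
  out
}

#' @export
print.sleep_journal <- function(x, ...) {
  cat(sprintf("<sleep_journal> %d nights, source = %s\n",
              nrow(x), attr(x, "source")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Caregiver observation sheet
#'
#' A 30-min awake/sleeping grid as filled by personal support workers: one
#' state per half-hour slot, with unfilled slots recorded as `"missing"`.
#'
#' @param slot_start `POSIXct` vector of slot start times, each on a half-hour
#'   boundary.
#' @param state character vector, each one of `"awake"`, `"sleeping"`,
#'   `"missing"`.
#'
#' @return data.frame of class `observation_sheet` with columns `slot_start`,
#'   `state`.
#' @export
observation_sheet <- function(slot_start, state) {
  stopifnot(inherits(slot_start, "POSIXct"),
            length(slot_start) == length(state))
  if (any(as.numeric(slot_start) %% 1800 != 0))
    stop("observation-sheet slots must start on the half hour", call. = FALSE)
  state <- as.character(state)
  if (!all(state %in% c("awake", "sleeping", "missing")))
    stop("`state` must be 'awake', 'sleeping' or 'missing'", call. = FALSE)
  out <- data.frame(slot_start = slot_start, state = state)
  out <- out[order(out$slot_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("observation_sheet", "data.frame")
  out
}

# 3 PM-anchored day label: the civil date of the window start.
# Used to match device and reference nights.
anchored_date <- function(t, anchor_hour = 15L) {
  as.Date(floor((as.numeric(t) - anchor_hour * 3600) / 86400),
          origin = "1970-01-01")
}
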