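#' Per-day absolute differences between device and reference sleep
#'
#' Matches two journals (device vs reference) on their 3 PM-anchored days
#' and reports per-day absolute differences of sleep onset, offset and
#' duration, in minutes. Days monitored in the reference journal on which
#' the device reported no sleep at all appear with `device_valid = FALSE`
#' and no differences; such days are excluded from means downstream.
#'
#' @param device a [sleep_journal()] as reported by the device (or
#'   surrogate).
#' @param reference the reference journal (self-report or recreated).
#'
#' @return data.frame of class `agreement_records`: `date`, `device_valid`,
#'   `onset_diff`, `offset_diff`, `duration_diff` (minutes, NA when the
#'   device reported nothing).
#' @export
#' @examples
#' ref <- sleep_journal(as.Date("2024-03-04"),
#'   as.POSIXct("2024-03-04 23:45:00", tz = "UTC"),
#'   as.POSIXct("2024-03-05 07:30:00", tz = "UTC"))
#' dev <- sleep_journal(as.Date("2024-03-04"),
#'   as.POSIXct("2024-03-05 02:43:00", tz = "UTC"),
#'   as.POSIXct("2024-03-05 07:30:00", tz = "UTC"), source = "device")
#' absolute_differences(dev, ref)
absolute_differences <- function(device, reference) {
  stopifnot(is.data.frame(device), is.data.frame(reference))
  if (!nrow(reference))
    stop("reference journal is empty: no overlapping days", call. = FALSE)
  m <- match(reference$date, device$date)
  valid <- !is.na(m)
  out <- data.frame(
    date = reference$date,
    device_valid = valid,
    onset_diff = NA_real_, offset_diff = NA_real_, duration_diff = NA_real_)
  if (any(valid)) {
    dv <- device[m[valid], , drop = FALSE]
    rf <- reference[valid, , drop = FALSE]
    out$onset_diff[valid] <-
      abs(as.numeric(dv$onset) - as.numeric(rf$onset)) / 60
    out$offset_diff[valid] <-
      abs(as.numeric(dv$offset) - as.numeric(rf$offset)) / 60
    out$duration_diff[valid] <- abs(dv$duration_min - rf$duration_min)
  }
  class(out) <- c("agreement_records", "data.frame")
  out
}

#' Summarise agreement records over valid days
#'
#' @param records an [absolute_differences()] table.
#' @return one-row data.frame of means and SDs of the three differences over
#'   valid days, plus `n_valid`, `n_total`.
#' @export
summarise_agreement <- function(records) {
  v <- records[records$device_valid, , drop = FALSE]
  stat <- function(x) c(mean(x), stats::sd(x))
  on <- stat(v$onset_diff); off <- stat(v$offset_diff)
  du <- stat(v$duration_diff)
  data.frame(onset_mean = on[1], onset_sd = on[2],
             offset_mean = off[1], offset_sd = off[2],
             duration_mean = du[1], duration_sd = du[2],
             n_valid = nrow(v), n_total = nrow(records))
}

#' Valid-day summary per subject and pooled
#'
#' A monitored day is valid when the device reported any sleep on it. The
#' pooled percentage is pooled valid over pooled total (not the mean of the
#' per-subject percentages), with percentages rounded half-up to integers.
#'
#' @param total integer vector of monitored days per subject.
#' @param valid integer vector of valid days per subject.
#' @param subject optional subject labels.
#'
#' @return data.frame with one row per subject plus a `"Total"` row: columns
#'   `subject`, `total_days`, `valid_days`, `percent`.
#' @export
#' @examples
#' valid_day_summary(c(14, 13, 10, 14, 14, 13, 14, 14),
#'                   c(14, 2, 10, 7, 12, 8, 11, 14))
valid_day_summary <- function(total, valid, subject = NULL) {
  total <- as.integer(total); valid <- as.integer(valid)
  stopifnot(length(total) == length(valid), all(valid <= total),
            all(total >= 0), all(valid >= 0))
  if (is.null(subject)) subject <- as.character(seq_along(total))
  pct <- function(v, t) if (t == 0) NA_real_ else floor(100 * v / t + 0.5)
  out <- data.frame(
    subject = c(subject, "Total"),
    total_days = c(total, sum(total)),
    valid_days = c(valid, sum(valid)),
    percent = c(mapply(pct, valid, total), pct(sum(valid), sum(total))))
  rownames(out) <- NULL
  out
}

#' One-tailed Welch two-sample t test
#'
#' Welch (unequal-variance) t test with a one-tailed p-value in the stated
#' direction, as used for group contrasts of sleep parameters and rhythm
#' indices. The degenerate case of two constant, identical samples is
#' reported with `p = 0.5` and flagged.
#'
#' @param group_a,group_b numeric samples (each of length >= 2).
#' @param direction `"a_greater"` tests the alternative mean(a) > mean(b);
#'   `"b_greater"` the reverse.
#' @param alpha significance level for the `significant` flag (default 0.05).
#'
#' @return data.frame of class `group_comparison`: group means and SDs,
#'   `t_statistic`, `df`, `p_one_tailed`, `direction`, `significant`,
#'   `degenerate`.
#' @export
one_tailed_t <- function(group_a, group_b,
                         direction = c("a_greater", "b_greater"),
                         alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  degenerate <- stats::var(group_a) == 0 && stats::var(group_b) == 0
  if (degenerate) {
    d <- mean(group_a) - mean(group_b)
    if (d == 0) {
      tt <- list(statistic = 0, parameter = NA_real_, p.value = 0.5)
    } else {
      hit <- (d > 0) == (direction == "a_greater")
      tt <- list(statistic = sign(d) * Inf, parameter = NA_real_,
                 p.value = if (hit) 0 else 1)
    }
  } else {
    tt <- stats::t.test(group_a, group_b,
                        alternative = if (direction == "a_greater") "greater"
                                      else "less",
                        var.equal = FALSE)
    degenerate <- FALSE
  }
  out <- data.frame(
    group_a_mean = mean(group_a), group_a_sd = stats::sd(group_a),
    group_b_mean = mean(group_b), group_b_sd = stats::sd(group_b),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_one_tailed = unname(tt$p.value), direction = direction,
    significant = unname(tt$p.value) < alpha, degenerate = degenerate)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length (>= 3), e.g. a circadian index
#'   against a sleep parameter across subjects.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in one of the inputs: correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
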