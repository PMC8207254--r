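# End-to-end pipeline: simulate -> analyze -> compare -> report.
# Each stage reads and writes only the package's own CSV formats, so a full
# run is reproducible from the YAML config and the seed alone.

#' Simulate a full run to disk
#'
#' Generates every configured subject and writes the five per-subject CSVs
#' (temperature, accelerometry, self-report journal, observation sheet,
#' ground-truth intervals) into `out_dir/<subject>/`. Writing is atomic: all
#' files land in a temporary directory first and are moved into place only
#' when every subject succeeded.
#'
#' @param config a [run_config()] (or path to its YAML file).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the vector of subject directories.
#' @export
simulate_run <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  h <- config_hash(unclass(config))
  stage <- tempfile("wristsleep_run_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  subj_names <- names(config$subjects)
  for (k in seq_along(subj_names)) {
    s <- subj_names[k]
    subj <- config$subjects[[s]]
    overrides <- subj[setdiff(names(subj), "phenotype")]
    cfg <- do.call(phenotype_config, c(list(subj$phenotype), overrides))
    sub <- generate_subject(cfg, n_days = config$n_days,
                            seed = config$seed + k - 1L,
                            accel_rate = config$accel_rate,
                            temp_step = config$temp_step)
    sd <- file.path(stage, s)
    dir.create(sd)
    write_temperature_csv(sub$temperature,
                          file.path(sd, "temperature.csv"), h)
    write_accel_csv(sub$accel, file.path(sd, "accel.csv"), h)
    write_journal_csv(sub$journal, file.path(sd, "journal.csv"), h)
    write_sheet_csv(sub$sheet, file.path(sd, "sheet.csv"), h)
    write_intervals_csv(sub$truth$sleep_intervals,
                        file.path(sd, "truth_intervals.csv"), h)
    message(sprintf("simulated %s (%s, %d days, seed %d)",
                    s, subj$phenotype, config$n_days,
                    config$seed + k - 1L))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in subj_names) {
    dest <- file.path(out_dir, s)
    unlink(dest, recursive = TRUE)
    if (!dir.create(dest) ||
        !all(file.copy(list.files(file.path(stage, s), full.names = TRUE),
                       dest)))
      stop("could not write to ", dest, call. = FALSE)
  }
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  invisible(file.path(out_dir, subj_names))
}

#' Analyze one subject directory
#'
#' Runs the temperature-rhythm and sleep-detection stages on the CSVs in
#' `subject_dir`: cleans and smooths the temperature, computes the rhythm
#' summary against the reference journal, epochs the accelerometry,
#' identifies sleep periods per 3 PM-anchored day, runs the surrogate device
#' detector, and recreates the journal from the observation sheet plus the
#' identified intervals. Results are written back into `subject_dir`.
#'
#' @param subject_dir directory produced by [simulate_run()] (or holding
#'   equivalently formatted CSVs).
#' @param config a [run_config()]; defaults to the one stored with the run.
#' @return invisibly, a list with `rhythm` (one-row data.frame),
#'   `intervals`, `device_journal`, `recreated_journal`.
#' @export
analyze_subject <- function(subject_dir, config = NULL) {
  if (is.null(config)) {
    cfg_path <- file.path(dirname(subject_dir), "run_config.yaml")
    config <- if (file.exists(cfg_path)) read_run_config(cfg_path)
              else run_config()
  }
  h <- config_hash(unclass(config))
  temp <- read_temperature_csv(file.path(subject_dir, "temperature.csv"))
  accel <- read_accel_csv(file.path(subject_dir, "accel.csv"))
  journal <- read_journal_csv(file.path(subject_dir, "journal.csv"))
  sheet <- read_sheet_csv(file.path(subject_dir, "sheet.csv"))

  cleaned <- median_smooth(clean_temperature(temp,
                                             floor = config$clean_floor))
  ref_int <- sleep_intervals(journal$onset, journal$offset)
  rhythm <- rhythm_summary(cleaned, ref_int, bin_width = config$bin_width)

  profile <- epoch_activity(accel, epoch_length = config$epoch_length,
                            static_threshold = config$static_threshold)
  seg <- segment_days(cleaned)
  seg <- seg[seg$complete, , drop = FALSE]
  ints <- list(); dev <- list()
  for (k in seq_len(nrow(seg))) {
    ints[[k]] <- identify_sleep_periods(
      profile, seg$window_start[k], seg$window_end[k],
      merge_tolerance = config$merge_tolerance,
      max_wake_gap = config$max_wake_gap,
      min_main_sleep = config$min_main_sleep, min_nap = config$min_nap)
    dev[[k]] <- surrogate_device_detect(
      profile, seg$window_start[k], seg$window_end[k],
      open_after = config$open_after, close_after = config$close_after)
  }
  intervals <- do.call(rbind, ints)
  class(intervals) <- c("sleep_intervals", "data.frame")
  device <- bind_journals(dev, "device")
  recreated <- recreate_journal(intervals, sheet)

  write_with_header(rhythm, file.path(subject_dir, "rhythm_summary.csv"), h)
  write_intervals_csv(intervals, file.path(subject_dir, "intervals.csv"), h)
  write_journal_csv(device, file.path(subject_dir, "device_journal.csv"), h)
  write_journal_csv(recreated,
                    file.path(subject_dir, "recreated_journal.csv"), h)
  invisible(list(rhythm = rhythm, intervals = intervals,
                 device_journal = device, recreated_journal = recreated))
}

bind_journals <- function(js, source) {
  js <- js[vapply(js, nrow, integer(1)) > 0L]
  if (!length(js)) return(sleep_journal(NULL, NULL, NULL, source = source))
  df <- do.call(rbind, lapply(js, as.data.frame))
  sleep_journal(df$date, df$onset, df$offset, n_wakes = df$n_wakes,
                quality = df$quality, source = source,
                duration_min = df$duration_min,
                low_confidence = df$low_confidence)
}

#' Compare a device journal with a reference journal
#'
#' @param device_path,reference_path journal CSV paths.
#' @param out_dir optional directory for the agreement CSVs.
#' @return list with `records` ([absolute_differences()]), `summary`
#'   ([summarise_agreement()]) and `valid_days` (one-subject
#'   [valid_day_summary()]).
#' @export
compare_journals <- function(device_path, reference_path, out_dir = NULL) {
  device <- read_journal_csv(device_path)
  reference <- read_journal_csv(reference_path)
  records <- absolute_differences(device, reference)
  summary <- summarise_agreement(records)
  vd <- valid_day_summary(nrow(records), sum(records$device_valid))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_with_header(records, file.path(out_dir, "agreement_records.csv"))
    write_with_header(summary, file.path(out_dir, "agreement_summary.csv"))
    write_with_header(vd, file.path(out_dir, "valid_days.csv"))
  }
  list(records = records, summary = summary, valid_days = vd)
}

#' Plot one day of wearable data
#'
#' Temperature trace over a 3 PM-anchored day with epoch activity underneath
#' and detected sleep shaded — the standard way to eyeball why a detector
#' called (or missed) a night.
#'
#' @param temp a cleaned [temperature_series()].
#' @param profile an [epoch_activity()] profile.
#' @param intervals detected [sleep_intervals()].
#' @param window_start,window_end day bounds.
#' @return a ggplot object.
#' @export
plot_day <- function(temp, profile, intervals, window_start, window_end) {
  tt <- series_times(temp)
  keep <- tt >= window_start & tt < window_end
  dtemp <- data.frame(time = tt[keep], value = temp$values[keep],
                      panel = "wrist temperature (degC)")
  pk <- profile$epoch_start >= window_start &
    profile$epoch_start < window_end
  dact <- data.frame(time = profile$epoch_start[pk],
                     value = profile$activity[pk],
                     panel = "epoch activity (g)")
  shade <- intervals[intervals$offset > window_start &
                       intervals$onset < window_end, , drop = FALSE]
  p <- ggplot2::ggplot(rbind(dtemp, dact),
                       ggplot2::aes(x = .data$time, y = .data$value))
  if (nrow(shade))
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(shade),
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "steelblue",
      inherit.aes = FALSE)
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Write a human-readable run report
#'
#' Walks every analyzed subject of a run directory, writes one daily trace
#' plot per complete day (`<subject>/day_<date>.pdf`) and a plain-text
#' summary (`report.txt`) listing rhythm indices and the valid-day table.
#' Missing optional outputs are skipped with a message.
#'
#' @param run_dir directory produced by [simulate_run()] +
#'   [analyze_subject()].
#' @return invisibly, the report path.
#' @export
report_run <- function(run_dir) {
  subjects <- list.dirs(run_dir, recursive = FALSE)
  lines <- c("wristsleep run report", strrep("=", 21), "")
  vd_tot <- 0L; vd_val <- 0L
  for (sd in subjects) {
    s <- basename(sd)
    lines <- c(lines, sprintf("subject %s", s))
    rp <- file.path(sd, "rhythm_summary.csv")
    if (file.exists(rp)) {
      r <- read_with_header(rp)
      lines <- c(lines, sprintf(
        paste0("  contrast %.2f degC, IS %.3f, IV %.3f, MESOR %.2f, ",
               "amplitude %.2f, acrophase %.0f min"),
        r$sleep_wake_diff, r$is_value, r$iv_value, r$mesor, r$amplitude,
        r$acrophase_min))
    } else {
      message("no rhythm summary for ", s, "; skipping")
    }
    dj <- file.path(sd, "device_journal.csv")
    jr <- file.path(sd, "journal.csv")
    if (file.exists(dj) && file.exists(jr)) {
      cmp <- compare_journals(dj, jr)
      nv <- cmp$valid_days$valid_days[1L]
      nt <- cmp$valid_days$total_days[1L]
      vd_tot <- vd_tot + nt; vd_val <- vd_val + nv
      lines <- c(lines, sprintf("  device-valid days: %d/%d (%.0f%%)",
                                nv, nt, 100 * nv / max(nt, 1L)))
    }
    tp <- file.path(sd, "temperature.csv")
    ip <- file.path(sd, "intervals.csv")
    ap <- file.path(sd, "accel.csv")
    if (file.exists(tp) && file.exists(ip) && file.exists(ap)) {
      temp <- clean_temperature(read_temperature_csv(tp))
      profile <- epoch_activity(read_accel_csv(ap))
      ints <- read_intervals_csv(ip)
      seg <- segment_days(temp)
      seg <- seg[seg$complete, , drop = FALSE]
      for (k in seq_len(nrow(seg))) {
        p <- plot_day(temp, profile, ints, seg$window_start[k],
                      seg$window_end[k])
        f <- file.path(sd, sprintf("day_%s.pdf",
                                   format(seg$window_start[k], "%Y-%m-%d")))
        ggplot2::ggsave(f, p, width = 7, height = 4)
      }
    }
    lines <- c(lines, "")
  }
  if (vd_tot > 0)
    lines <- c(lines, sprintf("pooled device-valid days: %d/%d (%.0f%%)",
                              vd_val, vd_tot, 100 * vd_val / vd_tot))
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(out)
}
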