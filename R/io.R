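# CSV interchange: plain CSV, ISO-8601 local timestamps, one comment-prefixed
# provenance header line carrying the run-config hash.

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")
parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S",
                                     tz = .tz)

write_with_header <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wristsleep %s config_hash=%s",
                     as.character(utils::packageVersion("wristsleep")),
                     if (is.null(config_hash)) "none" else config_hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_with_header <- function(path) {
  if (!file.exists(path))
    stop("missing input file: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Stable hash of a run configuration
#'
#' MD5 of the canonical YAML serialization of the config, embedded in every
#' output header for provenance.
#'
#' @param config a list (e.g. a [run_config()]).
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  flat <- config[order(names(config))]
  writeLines(yaml::as.yaml(flat), tmp)
  unname(tools::md5sum(tmp))
}

# --- per-signal writers / readers ----------------------------------------

#' Write / read wearable CSV files
#'
#' Plain-CSV interchange for every object the pipeline produces:
#' temperature (`timestamp,temp_c`), accelerometry
#' (`timestamp,x_g,y_g,z_g`), journals (`date,onset,offset,duration_min,
#' n_wakes,quality,low_confidence`), observation sheets (`slot_start,state`)
#' and sleep intervals (`onset,offset,kind,mean_activity_g,sleep_min`).
#' Timestamps are ISO-8601 local time; a comment-prefixed header line carries
#' the package version and config hash.
#'
#' @param x object to write.
#' @param path file path.
#' @param config_hash optional provenance hash (see [config_hash()]).
#' @return `write_*` return `path` invisibly; `read_*` return the rebuilt
#'   object.
#' @name wearable_io
NULL

#' @rdname wearable_io
#' @export
write_temperature_csv <- function(x, path, config_hash = NULL) {
  df <- as.data.frame(x)
  df$timestamp <- fmt_time(df$timestamp)
  write_with_header(df, path, config_hash)
  invisible(path)
}

#' @rdname wearable_io
#' @export
read_temperature_csv <- function(path) {
  df <- read_with_header(path)
  tt <- parse_time(df$timestamp)
  if (nrow(df) < 2L) stop("temperature CSV needs at least 2 rows",
                          call. = FALSE)
  step <- as.numeric(tt[2L]) - as.numeric(tt[1L])
  if (any(abs(diff(as.numeric(tt)) - step) > 1e-6))
    stop("temperature CSV is not uniformly sampled", call. = FALSE)
  temperature_series(tt[1L], step, df$temp_c)
}

#' @rdname wearable_io
#' @export
write_accel_csv <- function(x, path, config_hash = NULL) {
  df <- as.data.frame(x)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%OS3")
  write_with_header(df, path, config_hash)
  invisible(path)
}

#' @rdname wearable_io
#' @export
read_accel_csv <- function(path) {
  df <- read_with_header(path)
  tt <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = .tz)
  if (nrow(df) < 2L) stop("accelerometry CSV needs at least 2 rows",
                          call. = FALSE)
  rate <- 1 / (as.numeric(tt[2L]) - as.numeric(tt[1L]))
  accel_series(tt[1L], rate, as.matrix(df[, c("x_g", "y_g", "z_g")]))
}

#' @rdname wearable_io
#' @export
write_journal_csv <- function(x, path, config_hash = NULL) {
  df <- as.data.frame(x)
  df$onset <- fmt_time(df$onset); df$offset <- fmt_time(df$offset)
  df$source <- attr(x, "source")
  write_with_header(df, path, config_hash)
  invisible(path)
}

#' @rdname wearable_io
#' @export
read_journal_csv <- function(path) {
  df <- read_with_header(path)
  src <- if (nrow(df)) df$source[1L] else "self_report"
  if (!nrow(df)) return(sleep_journal(NULL, NULL, NULL, source = src))
  sleep_journal(as.Date(df$date), parse_time(df$onset),
                parse_time(df$offset), n_wakes = df$n_wakes,
                quality = df$quality, source = src,
                duration_min = df$duration_min,
                low_confidence = df$low_confidence)
}

#' @rdname wearable_io
#' @export
write_sheet_csv <- function(x, path, config_hash = NULL) {
  df <- as.data.frame(x)
  df$slot_start <- fmt_time(df$slot_start)
  write_with_header(df, path, config_hash)
  invisible(path)
}

#' @rdname wearable_io
#' @export
read_sheet_csv <- function(path) {
  df <- read_with_header(path)
  observation_sheet(parse_time(df$slot_start), df$state)
}

#' @rdname wearable_io
#' @export
write_intervals_csv <- function(x, path, config_hash = NULL) {
  df <- as.data.frame(x)
  names(df)[names(df) == "mean_activity"] <- "mean_activity_g"
  df$onset <- fmt_time(df$onset); df$offset <- fmt_time(df$offset)
  write_with_header(df, path, config_hash)
  invisible(path)
}

#' @rdname wearable_io
#' @export
read_intervals_csv <- function(path) {
  df <- read_with_header(path)
  if (!nrow(df)) return(sleep_intervals(NULL, NULL))
  sleep_intervals(parse_time(df$onset), parse_time(df$offset), df$kind,
                  mean_activity = df$mean_activity_g,
                  sleep_min = df$sleep_min)
}

# --- run configuration ----------------------------------------------------

#' Run configuration
#'
#' One object holding every tunable of the pipeline with its default, as
#' read from (or written to) a single YAML file: subjects to simulate
#' (phenotype + overrides), recording length, seed, accelerometer rate,
#' epoching and detection thresholds, IS/IV bin width, and t-test
#' directions.
#'
#' @param subjects named list: subject id -> list with at least `phenotype`,
#'   plus any [phenotype_config()] overrides.
#' @param n_days recording length in days.
#' @param seed base integer seed; subject k uses `seed + k - 1`.
#' @param accel_rate accelerometer rate, Hz.
#' @param temp_step temperature sampling interval, seconds.
#' @param epoch_length,static_threshold,merge_tolerance,max_wake_gap,min_main_sleep,min_nap
#'   detection tunables, see [epoch_activity()] and
#'   [identify_sleep_periods()].
#' @param open_after,close_after surrogate-detector tunables, see
#'   [surrogate_device_detect()].
#' @param bin_width IS/IV bin width, seconds.
#' @param clean_floor temperature cleaning floor, degC.
#' @param t_direction direction for group contrasts, see [one_tailed_t()].
#'
#' @return list of class `run_config`.
#' @export
run_config <- function(subjects = list(S1 = list(phenotype = "regular_young")),
                       n_days = 14L, seed = 1L, accel_rate = 25,
                       temp_step = 300, epoch_length = 30,
                       static_threshold = 0.02, merge_tolerance = 600,
                       max_wake_gap = 7200, min_main_sleep = 10800,
                       min_nap = 1200, open_after = 120L, close_after = 10L,
                       bin_width = 3600, clean_floor = 28,
                       t_direction = "a_greater") {
  cfg <- as.list(environment())
  if (!length(cfg$subjects) || is.null(names(cfg$subjects)) ||
      any(names(cfg$subjects) == ""))
    stop("config error: `subjects` must be a named list", call. = FALSE)
  for (s in names(cfg$subjects)) {
    ph <- cfg$subjects[[s]]$phenotype
    if (is.null(ph) ||
        !ph %in% c("regular_young", "regular_old", "fragmented_oawd"))
      stop("config error: subject '", s, "' needs a valid `phenotype`",
           call. = FALSE)
  }
  if (cfg$n_days < 1) stop("config error: n_days must be >= 1",
                           call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}
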