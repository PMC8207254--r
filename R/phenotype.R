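#' Sleeper-phenotype configuration
#'
#' Builds a validated phenotype configuration for the synthetic
#' wearable-data generator. Three named phenotypes ship with the package
#' (defaults in `inst/extdata/phenotypes.yaml`):
#'
#' * `regular_young` — consolidated quiet sleep around 00:32-07:55, large
#'   sleep/wake temperature contrast (2.48 degC);
#' * `regular_old` — earlier, longer sleep with brief periodic limb-movement
#'   bursts (~every 30 s over a 2.5-h window after onset), contrast 2.04 degC;
#' * `fragmented_oawd` — early onset, fragmented sleep (static episodes each
#'   under 30 min separated by movement), daytime naps, flat temperature
#'   rhythm (contrast 1.26 degC), and caregiver observation sheets only 40%
#'   filled.
#'
#' @param name one of `"regular_young"`, `"regular_old"`,
#'   `"fragmented_oawd"`.
#' @param ... overrides for individual fields (see the YAML file for the full
#'   list): `mean_onset`/`mean_offset` ("HH:MM"), `onset_sd`/`offset_sd`
#'   (minutes), `sleep_temp`/`wake_temp`/`cosinor_mesor`/`cosinor_amplitude`/
#'   `temp_noise_sd` (degC), `cosinor_acrophase` (minutes after midnight),
#'   `movement_mode` (`"quiet"`, `"periodic_30s"`, `"fragmented"`),
#'   `fragment_episode_max` (minutes), `nap_rate`/`shower_rate` (events/day),
#'   `sheet_fill_fraction` (0-1).
#'
#' @return list of class `phenotype_config`.
#' @export
#' @examples
#' cfg <- phenotype_config("regular_young", shower_rate = 0)
#' cfg$sleep_temp - cfg$wake_temp
phenotype_config <- function(name = c("regular_young", "regular_old",
                                      "fragmented_oawd"), ...) {
  name <- match.arg(name)
  defaults <- phenotype_defaults()[[name]]
  cfg <- utils::modifyList(defaults, list(...))
  unknown <- setdiff(names(list(...)), names(defaults))
  if (length(unknown))
    stop("unknown phenotype field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg$name <- name
  validate_phenotype(cfg)
}

#' Phenotype default table
#'
#' @return named list of default parameter lists, read from the YAML file
#'   shipped with the package.
#' @export
phenotype_defaults <- function() {
  path <- system.file("extdata", "phenotypes.yaml", package = "wristsleep",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}

validate_phenotype <- function(cfg) {
  num_pos <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("phenotype field `", f, "` must be a non-negative number",
           call. = FALSE)
  }
  for (f in c("onset_sd", "offset_sd", "temp_noise_sd", "cosinor_amplitude",
              "fragment_episode_max", "nap_rate", "shower_rate"))
    num_pos(f)
  if (cfg$sleep_temp <= cfg$wake_temp)
    stop("sleep_temp must exceed wake_temp: distal temperature is higher ",
         "during sleep", call. = FALSE)
  if (cfg$sheet_fill_fraction < 0 || cfg$sheet_fill_fraction > 1)
    stop("sheet_fill_fraction must lie in [0, 1]", call. = FALSE)
  if (!cfg$movement_mode %in% c("quiet", "periodic_30s", "fragmented"))
    stop("movement_mode must be 'quiet', 'periodic_30s' or 'fragmented'",
         call. = FALSE)
  if (cfg$cosinor_acrophase < 0 || cfg$cosinor_acrophase >= 1440)
    stop("cosinor_acrophase must lie in [0, 1440) minutes", call. = FALSE)
  for (f in c("mean_onset", "mean_offset")) parse_clock(cfg[[f]])
  class(cfg) <- "phenotype_config"
  cfg
}

#' @export
print.phenotype_config <- function(x, ...) {
  cat(sprintf(
    "<phenotype_config> %s: sleep %s-%s (SD %g/%g min), contrast %.2f degC, movement %s\n",
    x$name, x$mean_onset, x$mean_offset, x$onset_sd, x$offset_sd,
    x$sleep_temp - x$wake_temp, x$movement_mode))
  invisible(x)
}

# "HH:MM" -> seconds after midnight
parse_clock <- function(s) {
  if (is.numeric(s)) return(as.numeric(s))
  m <- regmatches(s, regexec("^([0-9]{1,2}):([0-9]{2})$", s))[[1]]
  if (length(m) != 3L)
    stop("clock times must be 'HH:MM', got '", s, "'", call. = FALSE)
  h <- as.numeric(m[2]); mi <- as.numeric(m[3])
  if (h > 23 || mi > 59) stop("invalid clock time '", s, "'", call. = FALSE)
  h * 3600 + mi * 60
}
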