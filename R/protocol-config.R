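#' Protocol configuration for feeding-microstructure analysis
#'
#' Bundles the operational constants of the home-cage feeding protocol:
#' the intermeal-interval (IMI) threshold and minimum meal size that define
#' a meal, the diet energy density, the light schedule, and the
#' fasting/refeeding timetable. Every other function in the package takes a
#' `protocol_config` so that a single object is the source of truth for
#' thresholds and time conventions.
#'
#' The defaults encode the standard paradigm for mice: bouts clustered
#' within 5 min form one meal, a meal must remove at least 0.050 g of food,
#' chow at 3.0 kCal/g, 12:12-h light cycle with lights on at 06:30, a 16-h
#' overnight fast starting at 16:00 with refeeding at 08:00, monitored for
#' 24 h in 2-h bins.
#'
#' @param imi_threshold_s Minimum intermeal interval, seconds. Bout gaps
#'   shorter than this join a cluster; gaps at or above it separate meals.
#' @param min_meal_mass_g Minimum meal size, grams. Clusters below this are
#'   kept as subthreshold clusters (their mass counts toward intake but they
#'   are excluded from meal-based metrics).
#' @param energy_density_kcal_g Diet energy density, kCal per gram.
#' @param lights_on,lights_off Clock times (`"HH:MM"`) of the light
#'   transitions. The photophase (diurnal period) is the half-open interval
#'   `[lights_on, lights_off)`; the scotophase (nocturnal) is the rest of
#'   the day. The two must tile the 24-h day.
#' @param recording_days Length of the ad libitum recording window, days.
#' @param fast_start,refeed_start Clock times of food removal and food
#'   return in the fasting protocol.
#' @param refeed_monitor_h Hours of refeeding monitored.
#' @param refeed_bin_h Width of the refeeding IMI bins, hours. Must divide
#'   `refeed_monitor_h` exactly.
#' @param meal_duration_mode Which quantity is reported as "meal duration":
#'   `"eating_time"` (sum of member bout durations, the default) or
#'   `"span"` (first-bout start to last-bout end). Both are always computed.
#'
#' @return An object of class `protocol_config` (a validated list; clock
#'   times are stored as decimal hours).
#' @examples
#' cfg <- protocol_config()
#' cfg$imi_threshold_s
#' @export
protocol_config <- function(imi_threshold_s = 300,
                            min_meal_mass_g = 0.050,
                            energy_density_kcal_g = 3.0,
                            lights_on = "06:30",
                            lights_off = "18:30",
                            recording_days = 14,
                            fast_start = "16:00",
                            refeed_start = "08:00",
                            refeed_monitor_h = 24,
                            refeed_bin_h = 2,
                            meal_duration_mode = c("eating_time", "span")) {
  meal_duration_mode <- match.arg(meal_duration_mode)
  cfg <- structure(
    list(
      imi_threshold_s = as.numeric(imi_threshold_s),
      min_meal_mass_g = as.numeric(min_meal_mass_g),
      energy_density_kcal_g = as.numeric(energy_density_kcal_g),
      lights_on_h = parse_clock(lights_on),
      lights_off_h = parse_clock(lights_off),
      recording_days = as.numeric(recording_days),
      fast_start_h = parse_clock(fast_start),
      refeed_start_h = parse_clock(refeed_start),
      refeed_monitor_h = as.numeric(refeed_monitor_h),
      refeed_bin_h = as.numeric(refeed_bin_h),
      meal_duration_mode = meal_duration_mode
    ),
    class = "protocol_config"
  )
  validate_protocol_config(cfg)
}

validate_protocol_config <- function(cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (!is.finite(cfg$imi_threshold_s) || cfg$imi_threshold_s <= 0)
    stop("`imi_threshold_s` must be a positive number of seconds.", call. = FALSE)
  if (!is.finite(cfg$min_meal_mass_g) || cfg$min_meal_mass_g < 0)
    stop("`min_meal_mass_g` must be non-negative.", call. = FALSE)
  if (!is.finite(cfg$energy_density_kcal_g) || cfg$energy_density_kcal_g <= 0)
    stop("`energy_density_kcal_g` must be positive.", call. = FALSE)
  if (isTRUE(all.equal(cfg$lights_on_h, cfg$lights_off_h)))
    stop("`lights_on` and `lights_off` must differ: the two photoperiods ",
         "must tile the 24-h day.", call. = FALSE)
  if (cfg$recording_days <= 0)
    stop("`recording_days` must be positive.", call. = FALSE)
  if (cfg$refeed_monitor_h <= 0 || cfg$refeed_bin_h <= 0)
    stop("refeeding monitor and bin widths must be positive.", call. = FALSE)
  n_bins <- cfg$refeed_monitor_h / cfg$refeed_bin_h
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("`refeed_monitor_h` must be an integer multiple of `refeed_bin_h`.",
         call. = FALSE)
  cfg
}

# "HH:MM" or "HH:MM:SS" -> decimal hours in [0, 24)
parse_clock <- function(x) {
  if (is.numeric(x)) {
    h <- as.numeric(x)
  } else {
    parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
    if (!length(parts) %in% 2:3 || anyNA(suppressWarnings(as.numeric(parts))))
      stop("Clock times must be \"HH:MM\" or \"HH:MM:SS\", got ", x, call. = FALSE)
    parts <- as.numeric(parts)
    h <- parts[1] + parts[2] / 60 + if (length(parts) == 3) parts[3] / 3600 else 0
  }
  if (h < 0 || h >= 24) stop("Clock time out of [0, 24): ", x, call. = FALSE)
  h
}

#' @export
print.protocol_config <- function(x, ...) {
  fmt_clock <- function(h) sprintf("%02d:%02d", floor(h), round((h %% 1) * 60))
  cat("<protocol_config>\n")
  cat(sprintf("  meal definition : gap < %g s joins a cluster; mass >= %.3f g qualifies\n",
              x$imi_threshold_s, x$min_meal_mass_g))
  cat(sprintf("  energy density  : %g kCal/g\n", x$energy_density_kcal_g))
  cat(sprintf("  light schedule  : on %s, off %s (photophase %g h)\n",
              fmt_clock(x$lights_on_h), fmt_clock(x$lights_off_h),
              photophase_length(x)))
  cat(sprintf("  recording       : %g days\n", x$recording_days))
  cat(sprintf("  fasting protocol: fast %s -> refeed %s, monitored %g h in %g-h bins\n",
              fmt_clock(x$fast_start_h), fmt_clock(x$refeed_start_h),
              x$refeed_monitor_h, x$refeed_bin_h))
  cat(sprintf("  meal duration   : %s\n", x$meal_duration_mode))
  invisible(x)
}

#' Read a protocol configuration from a YAML file
#'
#' All keys are optional; absent keys fall back to the [protocol_config()]
#' defaults. Recognised keys mirror the `protocol_config()` arguments.
#'
#' @param path Path to a YAML file.
#' @return A `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(protocol_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("Ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  do.call(protocol_config, raw[intersect(names(raw), known)])
}

#' Write a protocol configuration to a YAML file
#'
#' @param cfg A `protocol_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "protocol_config"))
  fmt_clock <- function(h) sprintf("%02d:%02d:%02.0f",
                                   floor(h), floor((h * 60) %% 60), (h * 3600) %% 60)
  out <- list(
    imi_threshold_s = cfg$imi_threshold_s,
    min_meal_mass_g = cfg$min_meal_mass_g,
    energy_density_kcal_g = cfg$energy_density_kcal_g,
    lights_on = fmt_clock(cfg$lights_on_h),
    lights_off = fmt_clock(cfg$lights_off_h),
    recording_days = cfg$recording_days,
    fast_start = fmt_clock(cfg$fast_start_h),
    refeed_start = fmt_clock(cfg$refeed_start_h),
    refeed_monitor_h = cfg$refeed_monitor_h,
    refeed_bin_h = cfg$refeed_bin_h,
    meal_duration_mode = cfg$meal_duration_mode
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

photophase_length <- function(cfg) {
  (cfg$lights_off_h - cfg$lights_on_h) %% 24
}

clock_hours <- function(t) {
  lt <- as.POSIXlt(t)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Zeitgeber time of a timestamp
#'
#' Hours elapsed since the most recent lights-on (zeitgeber time 0 =
#' lights-on). Periodic with period 24 h and continuous across midnight.
#'
#' @param t A `POSIXct` vector.
#' @param cfg A [protocol_config()].
#' @return Numeric vector of hours in `[0, 24)`.
#' @examples
#' cfg <- protocol_config()
#' zeitgeber_time(as.POSIXct("2024-01-01 06:30:00", tz = "UTC"), cfg) # 0
#' @export
zeitgeber_time <- function(t, cfg) {
  (clock_hours(t) - cfg$lights_on_h) %% 24
}

#' Photoperiod label of a timestamp
#'
#' Classifies instants as `"diurnal"` (photophase, lights on) or
#' `"nocturnal"` (scotophase). Light transitions use half-open intervals:
#' the instant of lights-off is nocturnal, the instant of lights-on is
#' diurnal, so every instant has exactly one label.
#'
#' @inheritParams zeitgeber_time
#' @return Character vector, `"diurnal"` or `"nocturnal"`.
#' @export
photoperiod_of <- function(t, cfg) {
  zt <- zeitgeber_time(t, cfg)
  ifelse(zt < photophase_length(cfg), "diurnal", "nocturnal")
}
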