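#' Per-animal feeding microstructure summary
#'
#' Aggregates a segmented meal series into the satiation/satiety metrics of
#' meal pattern analysis, stratified by photoperiod: meal frequency
#' (meals/day), mean meal size (kCal, the satiation readout), mean
#' intermeal interval (min, the satiety readout), mean meal duration,
#' mean feeding rate, and energy intake absolute (kCal/day) and normalized
#' to body weight (kCal/gBW/day).
#'
#' Conventions: per-meal means are over qualifying meals only, but intake
#' totals include subthreshold clusters (food removed is food eaten). Each
#' meal and cluster carries the photoperiod of its first bout; each IMI is
#' assigned to the photoperiod in which the interval begins. Strata with
#' zero meals report a count of 0 and `NA` means (missing, not zero), so
#' they never bias group averages of per-meal quantities.
#'
#' @param series A [segment_meals()] result.
#' @param animal Optional [animal_record()]; used for body-weight
#'   normalization via [mean_body_weight()].
#' @param window Length-2 `POSIXct` analysis window; defaults to the
#'   stream's recording window. Counts are normalized by its length in
#'   days.
#' @param cfg A [protocol_config()]; defaults to the config the series was
#'   segmented with.
#' @param bw_g Fallback single body weight (grams) when `animal` is absent.
#' @return A tibble with one row per stratum (`diurnal`, `nocturnal`,
#'   `daily`) and columns `animal_id, stratum, n_days, n_meals,
#'   meal_count_per_day, mean_meal_size_kcal, mean_imi_min, n_imi,
#'   mean_meal_duration_s, mean_feeding_rate_kcal_s, intake_kcal,
#'   intake_kcal_per_day, intake_kcal_per_gbw_per_day, mean_bw_g`.
#' @export
summarize_microstructure <- function(series, animal = NULL, window = NULL,
                                     cfg = series$config, bw_g = NULL) {
  stopifnot(inherits(series, "meal_series"))
  if (is.null(window)) window <- series$window
  if (anyNA(window))
    stop("an analysis window is required (the stream had no recording window).",
         call. = FALSE)
  n_days <- as.numeric(difftime(window[2], window[1], units = "days"))
  if (n_days <= 0) stop("analysis window has non-positive length.", call. = FALSE)
  bw <- if (!is.null(animal)) mean_body_weight(animal, window) else
    if (!is.null(bw_g)) as.numeric(bw_g) else NA_real_

  m <- series$meals
  s <- series$subthreshold
  imis <- series$imis
  in_win <- function(t) t >= window[1] & t < window[2]
  m <- m[in_win(m$t_first), , drop = FALSE]
  s <- s[in_win(s$t_first), , drop = FALSE]
  if (nrow(imis)) {
    imi_start <- series$meals$t_last[imis$meal_index]
    keep <- in_win(imi_start)
    imis <- imis[keep, , drop = FALSE]
  }

  one_stratum <- function(name) {
    mm <- if (name == "daily") m else m[m$photoperiod == name, , drop = FALSE]
    ss <- if (name == "daily") s else s[s$photoperiod == name, , drop = FALSE]
    ii <- if (name == "daily") imis else
      imis[imis$photoperiod == name, , drop = FALSE]
    n_meals <- nrow(mm)
    mean_or_na <- function(x) if (length(x[!is.na(x)])) mean(x, na.rm = TRUE) else NA_real_
    intake <- sum(mm$size_kcal) + sum(ss$size_kcal)
    tibble::tibble(
      animal_id = series$animal_id,
      stratum = name,
      n_days = n_days,
      n_meals = n_meals,
      meal_count_per_day = n_meals / n_days,
      mean_meal_size_kcal = if (n_meals) mean(mm$size_kcal) else NA_real_,
      mean_imi_min = if (nrow(ii)) mean(ii$interval_s) / 60 else NA_real_,
      n_imi = nrow(ii),
      mean_meal_duration_s = if (n_meals) mean(mm$duration_s) else NA_real_,
      mean_feeding_rate_kcal_s = mean_or_na(mm$feeding_rate_kcal_s),
      intake_kcal = intake,
      intake_kcal_per_day = intake / n_days,
      intake_kcal_per_gbw_per_day = intake / n_days / bw,
      mean_bw_g = bw
    )
  }
  dplyr::bind_rows(lapply(c("diurnal", "nocturnal", "daily"), one_stratum))
}

# measure (hours) of {t in [0, len_h)} with (z0 + t) mod 24 in [a, b)
hours_in_zt_bin <- function(z0, len_h, a, b) {
  ov <- function(x1, x2) max(0, min(x2, b) - max(x1, a))
  full <- floor(len_h / 24)
  rem <- len_h - 24 * full
  z0 <- z0 %% 24
  partial <- if (z0 + rem <= 24) ov(z0, z0 + rem) else
    ov(z0, 24) + ov(0, z0 + rem - 24)
  full * (b - a) + partial
}

#' Circadian profile of energy intake
#'
#' Accumulates bout-level intake (all bouts, including subthreshold
#' nibbles) into zeitgeber-time bins and averages across recording days,
#' yielding the circadian pattern of energy intake in kCal and, when a body
#' weight is available, kCal/gBW. Partial first/last days are handled by
#' weighting each bin by the time it was actually observed.
#'
#' @param stream A [bout_stream()].
#' @param cfg A [protocol_config()].
#' @param bin_width_h Bin width in hours; must divide 24.
#' @param window Analysis window, default the recording window.
#' @param animal,bw_g Body weight source as in
#'   [summarize_microstructure()].
#' @return A tibble with one row per bin: `zt_bin_start`, `zt_bin_mid`,
#'   `days_observed`, `intake_kcal` (mean per observed day),
#'   `intake_kcal_per_gbw`.
#' @export
circadian_profile <- function(stream, cfg, bin_width_h = 1, window = NULL,
                              animal = NULL, bw_g = NULL) {
  stopifnot(inherits(stream, "bout_stream"), inherits(cfg, "protocol_config"))
  nb <- 24 / bin_width_h
  if (abs(nb - round(nb)) > 1e-9)
    stop("`bin_width_h` must divide 24.", call. = FALSE)
  nb <- as.integer(round(nb))
  if (is.null(window)) window <- stream$window
  if (anyNA(window))
    stop("an analysis window is required.", call. = FALSE)
  bw <- if (!is.null(animal)) mean_body_weight(animal, window) else
    if (!is.null(bw_g)) as.numeric(bw_g) else NA_real_
  len_h <- as.numeric(difftime(window[2], window[1], units = "hours"))
  z0 <- zeitgeber_time(window[1], cfg)
  edges <- seq(0, 24, by = bin_width_h)
  b <- stream$bouts
  b <- b[b$t_start >= window[1] & b$t_start < window[2], , drop = FALSE]
  zt <- zeitgeber_time(b$t_start, cfg)
  bin <- pmin(findInterval(zt, edges), nb)
  kcal <- vapply(seq_len(nb), function(k)
    sum(b$mass_g[bin == k]) * cfg$energy_density_kcal_g, numeric(1))
  days_obs <- vapply(seq_len(nb), function(k)
    hours_in_zt_bin(z0, len_h, edges[k], edges[k + 1]) / bin_width_h,
    numeric(1))
  tibble::tibble(
    zt_bin_start = edges[-length(edges)],
    zt_bin_mid = edges[-length(edges)] + bin_width_h / 2,
    days_observed = days_obs,
    intake_kcal = ifelse(days_obs > 0, kcal / days_obs, NA_real_),
    intake_kcal_per_gbw = ifelse(days_obs > 0, kcal / days_obs / bw, NA_real_)
  )
}

#' Cumulative energy intake
#'
#' Right-continuous running total of energy removed, stepping at each bout
#' start. The final value equals the stream's total intake.
#'
#' @inheritParams circadian_profile
#' @return A tibble `t` (`POSIXct`), `cumulative_kcal`; the first row is
#'   the window start at 0 kCal when a window is known.
#' @export
cumulative_intake <- function(stream, cfg) {
  stopifnot(inherits(stream, "bout_stream"))
  b <- stream$bouts
  steps <- tibble::tibble(t = b$t_start,
                          cumulative_kcal = cumsum(b$mass_g) *
                            cfg$energy_density_kcal_g)
  if (!anyNA(stream$window)) {
    steps <- rbind(tibble::tibble(t = stream$window[1], cumulative_kcal = 0),
                   steps)
  }
  steps
}
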