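#' Cluster feeding bouts by the intermeal-interval threshold
#'
#' The core operational step of meal pattern analysis: a linear scan over
#' the time-ordered bouts joins consecutive bouts whose end-to-start gap is
#' shorter than the IMI threshold into one cluster; a gap at or above the
#' threshold starts a new cluster. Every bout belongs to exactly one
#' cluster. The gap is measured end-to-start, i.e.
#' `t_start[i+1] - (t_start[i] + duration[i])`, so time spent eating never
#' counts toward the interval.
#'
#' @param stream A [bout_stream()].
#' @param cfg A [protocol_config()]; `cfg$imi_threshold_s` is the join
#'   threshold and `cfg$min_meal_mass_g` sets the `qualifies` flag.
#' @return A tibble with one row per cluster: `cluster_id`, `bout_indices`
#'   (list-column of row indices into `stream$bouts`), `n_bouts`, `t_first`
#'   (first bout start), `t_last` (last bout end), `mass_g`, `size_kcal`
#'   (`mass_g * energy_density`), `eating_time_s` (sum of member bout
#'   durations), `span_s` (`t_last - t_first`), `qualifies`
#'   (`mass_g >= min_meal_mass_g`) and `photoperiod` (of `t_first`).
#' @examples
#' cfg <- protocol_config()
#' b <- tibble::tibble(
#'   t_start = as.POSIXct("2024-01-01 07:00:00", tz = "UTC") + c(0, 210),
#'   duration_s = c(10, 10), mass_g = c(0.03, 0.03))
#' cluster_bouts(bout_stream(b, "m1"), cfg)  # one cluster of 0.06 g
#' @export
cluster_bouts <- function(stream, cfg) {
  stopifnot(inherits(stream, "bout_stream"), inherits(cfg, "protocol_config"))
  b <- stream$bouts
  n <- nrow(b)
  empty <- tibble::tibble(
    cluster_id = integer(), bout_indices = list(), n_bouts = integer(),
    t_first = as.POSIXct(character()), t_last = as.POSIXct(character()),
    mass_g = numeric(), size_kcal = numeric(), eating_time_s = numeric(),
    span_s = numeric(), qualifies = logical(), photoperiod = character())
  if (n == 0) return(empty)
  t0 <- as.numeric(b$t_start)
  t_end <- t0 + b$duration_s
  if (n > 1) {
    gaps <- t0[-1] - t_end[-n]
    if (any(gaps < 0))
      stop("overlapping bouts (negative gap) in stream for animal ",
           stream$animal_id, call. = FALSE)
    cluster_id <- cumsum(c(1L, as.integer(gaps >= cfg$imi_threshold_s)))
  } else {
    cluster_id <- 1L
  }
  idx <- split(seq_len(n), cluster_id)
  first <- vapply(idx, `[`, integer(1), 1L)
  last <- vapply(idx, function(i) i[length(i)], integer(1))
  mass <- vapply(idx, function(i) sum(b$mass_g[i]), numeric(1))
  eating <- vapply(idx, function(i) sum(b$duration_s[i]), numeric(1))
  tibble::tibble(
    cluster_id = seq_along(idx),
    bout_indices = unname(idx),
    n_bouts = lengths(idx),
    t_first = b$t_start[first],
    t_last = b$t_start[last] + b$duration_s[last],
    mass_g = unname(mass),
    size_kcal = unname(mass) * cfg$energy_density_kcal_g,
    eating_time_s = unname(eating),
    span_s = as.numeric(b$t_start[last]) + b$duration_s[last] -
      as.numeric(b$t_start[first]),
    qualifies = unname(mass) >= cfg$min_meal_mass_g,
    photoperiod = photoperiod_of(b$t_start[first], cfg)
  )
}

#' Segment a bout stream into meals and intermeal intervals
#'
#' Applies the operational meal definition: bout clusters (see
#' [cluster_bouts()]) whose total mass reaches the minimum meal size are
#' meals; smaller clusters are kept as subthreshold clusters. Intermeal
#' intervals (IMIs) run from the end of one qualifying meal to the start of
#' the next qualifying meal — subthreshold clusters are transparent, so a
#' nibble between two meals does not reset the interval. Total mass is
#' conserved exactly: meal mass plus subthreshold mass equals total bout
#' mass.
#'
#' @inheritParams cluster_bouts
#' @return An object of class `meal_series`: a list with `animal_id`,
#'   `meals` (qualifying clusters, plus `meal_index`,
#'   `feeding_rate_kcal_s`, `duration_s` — the reporting duration selected
#'   by `cfg$meal_duration_mode` — and `imi_to_next_s` / `imi_photoperiod`
#'   for the interval to the following meal), `subthreshold` (non-qualifying
#'   clusters), `imis` (tibble `meal_index`, `interval_s`, `photoperiod` of
#'   the interval's start), `config` and `window`.
#' @export
segment_meals <- function(stream, cfg) {
  clusters <- cluster_bouts(stream, cfg)
  meals <- clusters[clusters$qualifies, , drop = FALSE]
  sub <- clusters[!clusters$qualifies, , drop = FALSE]
  n_m <- nrow(meals)
  meals$meal_index <- seq_len(n_m)
  meals$duration_s <- if (cfg$meal_duration_mode == "span") meals$span_s else
    meals$eating_time_s
  meals$feeding_rate_kcal_s <- feeding_rate(meals)
  if (n_m > 1) {
    interval <- as.numeric(meals$t_first[-1]) - as.numeric(meals$t_last[-n_m])
    imis <- tibble::tibble(
      meal_index = seq_len(n_m - 1),
      interval_s = interval,
      photoperiod = photoperiod_of(meals$t_last[-n_m], cfg))
  } else {
    imis <- tibble::tibble(meal_index = integer(), interval_s = numeric(),
                           photoperiod = character())
  }
  meals$imi_to_next_s <- c(imis$interval_s, NA_real_)[seq_len(n_m)]
  structure(list(animal_id = stream$animal_id, meals = meals,
                 subthreshold = sub, imis = imis, config = cfg,
                 window = stream$window),
            class = "meal_series")
}

#' @export
print.meal_series <- function(x, ...) {
  cat(sprintf(
    "<meal_series> animal %s: %d meals (%.2f kCal), %d subthreshold clusters (%.3f g), %d IMIs\n",
    x$animal_id, nrow(x$meals), sum(x$meals$size_kcal),
    nrow(x$subthreshold), sum(x$subthreshold$mass_g), nrow(x$imis)))
  invisible(x)
}

#' Feeding rate of meals
#'
#' Meal size divided by meal eating time (kCal/s). Degenerate meals with
#' zero eating time get `NA` rather than an infinite rate, and are excluded
#' from averaged rates downstream.
#'
#' @param meals A cluster/meal tibble with columns `size_kcal` and
#'   `eating_time_s` (as produced by [cluster_bouts()]).
#' @return Numeric vector of rates, kCal/s.
#' @export
feeding_rate <- function(meals) {
  ifelse(meals$eating_time_s > 0, meals$size_kcal / meals$eating_time_s,
         NA_real_)
}

#' Flatten a meal series into the meals table
#'
#' One row per cluster (qualifying meals and subthreshold clusters),
#' time-ordered, in the fixed export schema.
#'
#' @param series A [segment_meals()] result, or a list of them.
#' @return A tibble with columns `animal_id, meal_index, t_first, t_last,
#'   n_bouts, mass_g, size_kcal, eating_time_s, span_s, duration_s,
#'   feeding_rate_kcal_s, qualifies, photoperiod, imi_to_next_s`.
#' @export
meals_table <- function(series) {
  if (inherits(series, "meal_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    m <- s$meals
    sub <- s$subthreshold
    if (nrow(sub)) {
      sub$meal_index <- NA_integer_
      sub$duration_s <- if (s$config$meal_duration_mode == "span") sub$span_s else
        sub$eating_time_s
      sub$feeding_rate_kcal_s <- NA_real_
      sub$imi_to_next_s <- NA_real_
    }
    cols <- c("meal_index", "t_first", "t_last", "n_bouts", "mass_g",
              "size_kcal", "eating_time_s", "span_s", "duration_s",
              "feeding_rate_kcal_s", "qualifies", "photoperiod",
              "imi_to_next_s")
    out <- rbind(m[cols], if (nrow(sub)) sub[cols])
    out <- out[order(out$t_first), ]
    tibble::add_column(out, animal_id = s$animal_id, .before = 1)
  })
  dplyr::bind_rows(rows)
}
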