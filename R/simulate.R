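#' Specification for the synthetic bout-stream generator
#'
#' Describes an alternating-renewal feeding process: intermeal intervals
#' drawn from photoperiod-specific gamma distributions, meals of
#' gamma-distributed caloric size eaten as 1 + Poisson bouts separated by
#' truncated-exponential within-meal gaps, bout durations set by a fixed
#' intake rate, and an optional superposed nibbling process of isolated
#' subthreshold bouts. Defaults are calibrated to ad libitum chow feeding
#' in adult mice: a ~70 min nocturnal intermeal interval, meals of
#' ~0.4-0.55 kCal, and ~13-16 meals per day.
#'
#' In `recoverable` mode the generator enforces the invariants the meal
#' definition assumes — between-meal gaps at or above the IMI threshold,
#' within-meal gaps strictly below it, meal masses at or above the minimum
#' meal size, and nibbles isolated from meals by at least the threshold —
#' so segmentation must reproduce the ground-truth meal table exactly.
#'
#' @param seed Integer; fully determines the output.
#' @param n_animals,days Cohort size and recording length.
#' @param nocturnal,diurnal Per-photoperiod parameter lists with elements
#'   `mean_imi_min` (gamma mean), `imi_shape`, `meal_size_mean_kcal`
#'   (gamma mean) and `meal_size_shape`.
#' @param bouts_per_meal_lambda Poisson mean; bouts per meal = 1 + Poisson.
#' @param within_meal_gap_mean_s Mean of the (truncated) exponential
#'   within-meal gap, seconds.
#' @param intake_rate_kcal_s Eating rate; bout duration = bout energy /
#'   rate.
#' @param nibble_rate_per_day Expected isolated subthreshold bouts per day.
#' @param nibble_mass_range_g Uniform mass range for nibbles; must stay
#'   below the minimum meal size.
#' @param recoverable Enforce exact-recovery invariants (see above).
#' @param genotype,sex,age_weeks Metadata stamped on every generated
#'   animal.
#' @param bw Body-weight bookkeeping model: `initial_g`, `drift_g_day`
#'   (linear ad libitum trend), `fast_loss_frac` (fraction of BW lost over
#'   a fast) and `regain_h` (hours to regain it linearly during
#'   refeeding).
#' @param refeed Optional refeeding scenario for [simulate_refeed()]:
#'   a list with `suppression` (fractional IMI shortening on food return),
#'   `recovery_h` (hours after refeed at which the IMI multiplier steps
#'   back to 1), `overshoot` (late multiplier > 1) and optionally
#'   `overshoot_start_h` (default 18).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_animals = 10, days = 14,
                           nocturnal = list(mean_imi_min = 70, imi_shape = 4,
                                            meal_size_mean_kcal = 0.55,
                                            meal_size_shape = 6),
                           diurnal = list(mean_imi_min = 180, imi_shape = 4,
                                          meal_size_mean_kcal = 0.40,
                                          meal_size_shape = 6),
                           bouts_per_meal_lambda = 2,
                           within_meal_gap_mean_s = 30,
                           intake_rate_kcal_s = 0.0017,
                           nibble_rate_per_day = 5,
                           nibble_mass_range_g = c(0.005, 0.045),
                           recoverable = TRUE,
                           genotype = "control", sex = "male",
                           age_weeks = 10,
                           bw = list(initial_g = 30, drift_g_day = 0.05,
                                     fast_loss_frac = 0.10, regain_h = 24),
                           refeed = NULL) {
  fill <- function(given, default) utils::modifyList(default, as.list(given))
  pp_default <- list(mean_imi_min = 70, imi_shape = 4,
                     meal_size_mean_kcal = 0.5, meal_size_shape = 6)
  spec <- structure(list(
    seed = as.integer(seed), n_animals = as.integer(n_animals),
    days = as.numeric(days),
    nocturnal = fill(nocturnal, pp_default),
    diurnal = fill(diurnal, pp_default),
    bouts_per_meal_lambda = as.numeric(bouts_per_meal_lambda),
    within_meal_gap_mean_s = as.numeric(within_meal_gap_mean_s),
    intake_rate_kcal_s = as.numeric(intake_rate_kcal_s),
    nibble_rate_per_day = as.numeric(nibble_rate_per_day),
    nibble_mass_range_g = as.numeric(nibble_mass_range_g),
    recoverable = isTRUE(recoverable),
    genotype = genotype, sex = sex, age_weeks = as.numeric(age_weeks),
    bw = fill(bw, list(initial_g = 30, drift_g_day = 0.05,
                       fast_loss_frac = 0.10, regain_h = 24)),
    refeed = refeed
  ), class = "generator_spec")
  validate_generator_spec(spec)
}

validate_generator_spec <- function(spec, cfg = protocol_config()) {
  pos <- function(x, nm) if (!all(is.finite(x)) || any(x <= 0))
    stop("generator parameter `", nm, "` must be strictly positive.",
         call. = FALSE)
  for (pp in c("nocturnal", "diurnal")) {
    pos(spec[[pp]]$mean_imi_min, paste0(pp, "$mean_imi_min"))
    pos(spec[[pp]]$imi_shape, paste0(pp, "$imi_shape"))
    pos(spec[[pp]]$meal_size_mean_kcal, paste0(pp, "$meal_size_mean_kcal"))
    pos(spec[[pp]]$meal_size_shape, paste0(pp, "$meal_size_shape"))
  }
  pos(spec$bouts_per_meal_lambda, "bouts_per_meal_lambda")
  pos(spec$within_meal_gap_mean_s, "within_meal_gap_mean_s")
  pos(spec$intake_rate_kcal_s, "intake_rate_kcal_s")
  if (spec$nibble_rate_per_day < 0)
    stop("`nibble_rate_per_day` must be non-negative.", call. = FALSE)
  if (spec$n_animals < 1 || spec$days <= 0)
    stop("need at least one animal and a positive number of days.",
         call. = FALSE)
  if (spec$recoverable) {
    for (pp in c("nocturnal", "diurnal")) {
      mean_mass <- spec[[pp]]$meal_size_mean_kcal / cfg$energy_density_kcal_g
      if (mean_mass < cfg$min_meal_mass_g)
        stop("inconsistent spec: recoverable mode with ", pp,
             " mean meal mass (", signif(mean_mass, 3),
             " g) below the minimum meal size (", cfg$min_meal_mass_g,
             " g).", call. = FALSE)
    }
    if (max(spec$nibble_mass_range_g) >= cfg$min_meal_mass_g)
      stop("inconsistent spec: nibble masses must stay below the minimum ",
           "meal size in recoverable mode.", call. = FALSE)
  }
  if (!is.null(spec$refeed)) {
    rf <- spec$refeed
    if (is.null(rf$suppression) || is.null(rf$recovery_h) ||
        is.null(rf$overshoot))
      stop("`refeed` scenario needs `suppression`, `recovery_h` and ",
           "`overshoot`.", call. = FALSE)
    if (rf$suppression < 0 || rf$suppression >= 1)
      stop("`refeed$suppression` must be in [0, 1).", call. = FALSE)
    if (rf$overshoot <= 0) stop("`refeed$overshoot` must be positive.",
                                call. = FALSE)
  }
  spec
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> seed %d: %d animal(s) x %g day(s), %s %s %g wk\n",
              x$seed, x$n_animals, x$days, x$genotype, x$sex, x$age_weeks))
  cat(sprintf("  nocturnal: IMI %g min (shape %g), meals %g kCal (shape %g)\n",
              x$nocturnal$mean_imi_min, x$nocturnal$imi_shape,
              x$nocturnal$meal_size_mean_kcal, x$nocturnal$meal_size_shape))
  cat(sprintf("  diurnal  : IMI %g min (shape %g), meals %g kCal (shape %g)\n",
              x$diurnal$mean_imi_min, x$diurnal$imi_shape,
              x$diurnal$meal_size_mean_kcal, x$diurnal$meal_size_shape))
  cat(sprintf("  bouts/meal 1+Pois(%g), gaps ~Exp(%g s), rate %g kCal/s, nibbles %g/day\n",
              x$bouts_per_meal_lambda, x$within_meal_gap_mean_s,
              x$intake_rate_kcal_s, x$nibble_rate_per_day))
  cat(sprintf("  recoverable mode: %s\n", ifelse(x$recoverable, "on", "off")))
  if (!is.null(x$refeed))
    cat(sprintf("  refeed scenario: suppression %g, recovery %g h, overshoot %g\n",
                x$refeed$suppression, x$refeed$recovery_h, x$refeed$overshoot))
  invisible(x)
}

# gamma draw parameterised by mean and shape
rgamma_mean <- function(n, mean, shape) stats::rgamma(n, shape = shape,
                                                      rate = shape / mean)

# exponential truncated to (0, upper); inverse-CDF so it is exact
rexp_trunc <- function(n, mean, upper) {
  u <- stats::runif(n)
  -mean * log(1 - u * (1 - exp(-upper / mean)))
}

sim_origin <- function(cfg) {
  as.POSIXct("2024-01-01 00:00:00", tz = "UTC") + cfg$lights_on_h * 3600
}

# one animal's ad libitum stream; imi_multiplier rescales the drawn IMIs
# as a function of hours since `t0`, and pp_override pins the parameter
# set (both used by the refeeding scenario, whose IMIs are baseline x
# multiplier irrespective of clock time)
sim_one_stream <- function(spec, cfg, t0, end, imi_multiplier = NULL,
                           pp_override = NULL) {
  thr <- cfg$imi_threshold_s
  eps <- 1e-6
  bout_rows <- list()
  meal_rows <- list()
  t_cursor <- as.numeric(t0)
  prev_meal_end <- NA_real_
  k <- 0L
  repeat {
    pp <- if (!is.null(pp_override)) pp_override else
      photoperiod_of(as.POSIXct(t_cursor, tz = "UTC"), cfg)
    par <- spec[[pp]]
    imi <- rgamma_mean(1, par$mean_imi_min * 60, par$imi_shape)
    if (!is.null(imi_multiplier))
      imi <- imi * imi_multiplier((t_cursor - as.numeric(t0)) / 3600)
    if (spec$recoverable) imi <- max(imi, thr + eps)
    meal_start <- t_cursor + imi
    if (meal_start >= as.numeric(end)) break
    # meal size follows the photoperiod the meal starts in (the label the
    # analysis assigns), not the photoperiod the interval was drawn in
    pp_meal <- if (!is.null(pp_override)) pp_override else
      photoperiod_of(as.POSIXct(meal_start, tz = "UTC"), cfg)
    par_m <- spec[[pp_meal]]
    size <- rgamma_mean(1, par_m$meal_size_mean_kcal, par_m$meal_size_shape)
    mass <- size / cfg$energy_density_kcal_g
    if (spec$recoverable && mass < cfg$min_meal_mass_g) {
      mass <- cfg$min_meal_mass_g * (1 + 1e-6)
      size <- mass * cfg$energy_density_kcal_g
    }
    n_b <- 1L + stats::rpois(1, spec$bouts_per_meal_lambda)
    w <- stats::runif(n_b, 0.2, 1)            # bout mass proportions
    b_mass <- mass * w / sum(w)
    b_dur <- b_mass * cfg$energy_density_kcal_g / spec$intake_rate_kcal_s
    gaps <- if (n_b > 1)
      rexp_trunc(n_b - 1, spec$within_meal_gap_mean_s, thr - 1) else numeric()
    starts <- meal_start + c(0, cumsum(b_dur[-n_b] + gaps))
    meal_end <- starts[n_b] + b_dur[n_b]
    if (meal_end > as.numeric(end)) break     # discard partial final meal
    k <- k + 1L
    bout_rows[[k]] <- data.frame(t_start = starts, duration_s = b_dur,
                                 mass_g = b_mass)
    meal_rows[[k]] <- data.frame(
      meal_index = k, t_first = meal_start, t_last = meal_end,
      n_bouts = n_b, mass_g = mass,
      size_kcal = mass * cfg$energy_density_kcal_g,
      eating_time_s = sum(b_dur),
      photoperiod = photoperiod_of(as.POSIXct(meal_start, tz = "UTC"), cfg),
      imi_before_s = if (is.na(prev_meal_end)) NA_real_ else
        meal_start - prev_meal_end)
    prev_meal_end <- meal_end
    t_cursor <- meal_end
  }
  bouts <- if (k) do.call(rbind, bout_rows) else
    data.frame(t_start = numeric(), duration_s = numeric(), mass_g = numeric())
  meals <- if (k) do.call(rbind, meal_rows) else
    data.frame(meal_index = integer(), t_first = numeric(), t_last = numeric(),
               n_bouts = integer(), mass_g = numeric(), size_kcal = numeric(),
               eating_time_s = numeric(), photoperiod = character(),
               imi_before_s = numeric())
  list(bouts = bouts, meals = meals)
}

# superpose isolated subthreshold nibbles; in recoverable mode each nibble
# keeps >= thr clearance from every meal, every other nibble, and both
# window edges, so the detected meal/IMI structure is untouched
sim_nibbles <- function(spec, cfg, t0, end, meals) {
  n <- stats::rpois(1, spec$nibble_rate_per_day *
                      as.numeric(end - t0, units = "days"))
  if (n == 0)
    return(data.frame(t_start = numeric(), duration_s = numeric(),
                      mass_g = numeric()))
  thr <- cfg$imi_threshold_s
  lo <- as.numeric(t0)
  hi <- as.numeric(end)
  placed_start <- numeric()
  placed_end <- numeric()
  rows <- list()
  attempts <- 0L
  while (length(rows) < n && attempts < 200L * n) {
    attempts <- attempts + 1L
    mass <- stats::runif(1, spec$nibble_mass_range_g[1],
                         spec$nibble_mass_range_g[2])
    dur <- mass * cfg$energy_density_kcal_g / spec$intake_rate_kcal_s
    ts <- stats::runif(1, lo, hi - dur)
    te <- ts + dur
    if (spec$recoverable) {
      clear <- function(s, e) all(ts >= e + thr + 1 | te <= s - thr - 1)
      ok <- (ts >= lo + 1) && (te <= hi - 1) &&
        (nrow(meals) == 0 || clear(meals$t_first, meals$t_last)) &&
        (!length(placed_start) || clear(placed_start, placed_end))
      if (!ok) next
    }
    placed_start <- c(placed_start, ts)
    placed_end <- c(placed_end, te)
    rows[[length(rows) + 1L]] <- data.frame(t_start = ts, duration_s = dur,
                                            mass_g = mass)
  }
  do.call(rbind, rows)
}

sim_bw_series <- function(spec, t0, days) {
  d <- seq(0, floor(days))
  tibble::tibble(timestamp = t0 + d * 86400,
                 bw_g = spec$bw$initial_g + spec$bw$drift_g_day * d)
}

#' Simulate an ad libitum cohort of bout streams
#'
#' Runs the alternating-renewal feeding process of a [generator_spec()]
#' for each animal, with per-animal subseeds derived from the master seed
#' so animals are independent and the whole output is reproducible
#' bit-for-bit from `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @param cfg A [protocol_config()]. The recording window starts at
#'   lights-on and lasts `spec$days` days.
#' @return A list with `streams` (named list of [bout_stream()]),
#'   `animals` (named list of [animal_record()]), and `truth`: a list with
#'   `true_meals` (tibble: `animal_id, meal_index, t_first, t_last,
#'   n_bouts, mass_g, size_kcal, eating_time_s, photoperiod`), `true_imis`
#'   (tibble: `animal_id, meal_index, interval_s, photoperiod` — the
#'   interval following each meal) and `spec`.
#' @examples
#' sim <- simulate_cohort(generator_spec(seed = 7, n_animals = 2, days = 2),
#'                        protocol_config())
#' sim$streams[[1]]
#' @export
simulate_cohort <- function(spec, cfg = protocol_config()) {
  stopifnot(inherits(spec, "generator_spec"))
  validate_generator_spec(spec, cfg)
  set.seed(spec$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, spec$n_animals)
  t0 <- sim_origin(cfg)
  end <- t0 + spec$days * 86400
  streams <- list()
  animals <- list()
  meal_tabs <- list()
  for (a in seq_len(spec$n_animals)) {
    id <- sprintf("animal_%02d", a)
    set.seed(subseeds[a])
    sim <- sim_one_stream(spec, cfg, t0, end)
    nib <- sim_nibbles(spec, cfg, t0, end, sim$meals)
    bouts <- rbind(sim$bouts, nib)
    bouts$t_start <- as.POSIXct(bouts$t_start, tz = "UTC",
                                origin = "1970-01-01")
    streams[[id]] <- bout_stream(bouts, id, window = c(t0, end))
    animals[[id]] <- animal_record(id, genotype = spec$genotype,
                                   sex = spec$sex,
                                   age_weeks = spec$age_weeks,
                                   body_weight = sim_bw_series(spec, t0,
                                                               spec$days))
    m <- sim$meals
    if (nrow(m)) m$animal_id <- id
    meal_tabs[[id]] <- m
  }
  all_meals <- dplyr::bind_rows(meal_tabs)
  truth <- build_truth(all_meals, spec, cfg)
  list(streams = streams, animals = animals, truth = truth)
}

build_truth <- function(all_meals, spec, cfg) {
  if (nrow(all_meals)) {
    all_meals$t_first <- as.POSIXct(all_meals$t_first, tz = "UTC",
                                    origin = "1970-01-01")
    all_meals$t_last <- as.POSIXct(all_meals$t_last, tz = "UTC",
                                   origin = "1970-01-01")
    true_meals <- tibble::as_tibble(all_meals[c(
      "animal_id", "meal_index", "t_first", "t_last", "n_bouts", "mass_g",
      "size_kcal", "eating_time_s", "photoperiod")])
    imi <- all_meals[!is.na(all_meals$imi_before_s), ]
    true_imis <- tibble::tibble(
      animal_id = imi$animal_id,
      meal_index = imi$meal_index - 1L,
      interval_s = imi$imi_before_s,
      photoperiod = photoperiod_of(imi$t_first - imi$imi_before_s, cfg))
  } else {
    true_meals <- tibble::tibble()
    true_imis <- tibble::tibble()
  }
  list(true_meals = true_meals, true_imis = true_imis, spec = spec)
}

#' Simulate a fasting-refeeding episode
#'
#' Generates, for each animal, a stream spanning the day before the fast,
#' the fast itself (constructively bout-free) and the refeeding monitor
#' window. During refeeding the intermeal intervals are the ad libitum
#' draws multiplied by a three-component step curve: `1 - suppression`
#' from food return until `recovery_h`, 1 from `recovery_h` until
#' `overshoot_start_h`, and `overshoot` thereafter. The injected curve is
#' recorded in the ground truth so recovered kinetics can be scored
#' against it. Body weights at the fast start and refeed start follow the
#' spec's bookkeeping model (`fast_loss_frac`).
#'
#' @inheritParams simulate_cohort
#' @return As [simulate_cohort()], with `truth$injected` holding the
#'   scenario (`suppression`, `recovery_h`, `overshoot`,
#'   `overshoot_start_h`) and `truth$refeed_time` / `truth$fast_time` the
#'   protocol instants.
#' @export
simulate_refeed <- function(spec, cfg = protocol_config()) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(spec$refeed))
    stop("`spec$refeed` scenario is required for simulate_refeed().",
         call. = FALSE)
  validate_generator_spec(spec, cfg)
  rf <- spec$refeed
  overshoot_start <- if (!is.null(rf$overshoot_start_h)) rf$overshoot_start_h
    else 18
  multiplier <- function(h) ifelse(h < rf$recovery_h, 1 - rf$suppression,
                                   ifelse(h < overshoot_start, 1,
                                          rf$overshoot))
  set.seed(spec$seed + 1L)
  subseeds <- sample.int(.Machine$integer.max - 1L, spec$n_animals)
  t0 <- sim_origin(cfg)                         # lights-on, day 0
  fast_time <- next_clock_time(t0, cfg$fast_start_h)
  refeed_time <- next_clock_time(fast_time, cfg$refeed_start_h)
  end <- refeed_time + cfg$refeed_monitor_h * 3600
  streams <- list()
  animals <- list()
  meal_tabs <- list()
  for (a in seq_len(spec$n_animals)) {
    id <- sprintf("animal_%02d", a)
    set.seed(subseeds[a])
    pre <- sim_one_stream(spec, cfg, t0, fast_time)
    post <- sim_one_stream(spec, cfg, refeed_time, end,
                           imi_multiplier = multiplier,
                           pp_override = "nocturnal")
    nib_pre <- sim_nibbles(spec, cfg, t0, fast_time, pre$meals)
    bouts <- rbind(pre$bouts, nib_pre, post$bouts)
    bouts$t_start <- as.POSIXct(bouts$t_start, tz = "UTC",
                                origin = "1970-01-01")
    streams[[id]] <- bout_stream(bouts, id, window = c(t0, end))
    bw0 <- spec$bw$initial_g
    bw_fast <- bw0 * (1 - spec$bw$fast_loss_frac)
    regain_end <- refeed_time + spec$bw$regain_h * 3600
    bw_tab <- tibble::tibble(
      timestamp = c(fast_time, refeed_time, regain_end),
      bw_g = c(bw0, bw_fast, bw0))
    animals[[id]] <- animal_record(id, genotype = spec$genotype,
                                   sex = spec$sex,
                                   age_weeks = spec$age_weeks,
                                   body_weight = bw_tab)
    m <- rbind(pre$meals, post$meals)
    if (nrow(m)) {
      m$meal_index <- seq_len(nrow(m))
      m$animal_id <- id
      # the fast gap is not an IMI: blank the interval into the first
      # post-refeed meal
      first_post <- which(m$t_first >= as.numeric(refeed_time))[1]
      if (!is.na(first_post)) m$imi_before_s[first_post] <- NA_real_
    }
    meal_tabs[[id]] <- m
  }
  truth <- build_truth(dplyr::bind_rows(meal_tabs), spec, cfg)
  truth$injected <- list(suppression = rf$suppression,
                         recovery_h = rf$recovery_h,
                         overshoot = rf$overshoot,
                         overshoot_start_h = overshoot_start)
  truth$refeed_time <- refeed_time
  truth$fast_time <- fast_time
  list(streams = streams, animals = animals, truth = truth)
}

#' Cohort presets mirroring a genotype x age x sex study design
#'
#' Convenience [generator_spec()] presets for the six cohort cells of a
#' two-genotype (control vs. knockout), three-age (10, 20, 30 wk) design,
#' per sex. The presets are qualitative calibrations, not ground truth:
#' knockouts eat larger, less frequent meals (reduced satiation at
#' conserved satiety), with the shift growing with age, and females eat
#' slightly larger nocturnal meals than males.
#'
#' @param sex `"male"` or `"female"`.
#' @param seed Master seed; each cell gets a distinct derived seed.
#' @param n_animals,days Passed through to every cell.
#' @return A named list of `generator_spec`, e.g.
#'   `control_10wk, knockout_10wk, ...`.
#' @export
cohort_presets <- function(sex = c("male", "female"), seed = 1L,
                           n_animals = 10, days = 14) {
  sex <- match.arg(sex)
  ages <- c(10, 20, 30)
  size_shift <- c(control = 1, knockout = 1.18)       # satiation deficit
  age_gain <- c(`10` = 1, `20` = 1.08, `30` = 1.18)
  sex_gain <- if (sex == "female") 1.1 else 1
  bw0 <- if (sex == "female") 25 else 30
  out <- list()
  i <- 0L
  for (gt in c("control", "knockout")) {
    for (age in ages) {
      i <- i + 1L
      base_size <- 0.5 * age_gain[[as.character(age)]] * sex_gain *
        size_shift[[gt]]
      imi_scale <- if (gt == "knockout") 1.15 else 1   # fewer meals
      out[[paste0(gt, "_", age, "wk")]] <- generator_spec(
        seed = seed + 101L * i,
        n_animals = n_animals, days = days,
        nocturnal = list(mean_imi_min = 70 * imi_scale, imi_shape = 4,
                         meal_size_mean_kcal = base_size * 1.1,
                         meal_size_shape = 6),
        diurnal = list(mean_imi_min = 180 * imi_scale, imi_shape = 4,
                       meal_size_mean_kcal = base_size * 0.75,
                       meal_size_shape = 6),
        genotype = gt, sex = sex, age_weeks = age,
        bw = list(initial_g = bw0 + 0.2 * (age - 10) +
                    ifelse(gt == "knockout", 0.15 * (age - 10), 0),
                  drift_g_day = 0.05, fast_loss_frac = 0.10, regain_h = 24))
    }
  }
  out
}

#' Write generator ground truth to CSV
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param path Output CSV path for the true meal table.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  tm <- truth$true_meals
  tm$t_first <- format(tm$t_first, "%Y-%m-%d %H:%M:%OS6")
  tm$t_last <- format(tm$t_last, "%Y-%m-%d %H:%M:%OS6")
  utils::write.csv(tm, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
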