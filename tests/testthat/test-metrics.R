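day0 <- ts0("2024-01-01 06:30:00")
win14 <- c(day0, day0 + 14 * 86400)

# one 0.06-g meal per night at 20:00, for `days` days
nightly_series <- function(days = 14) {
  offsets <- (seq_len(days) - 1) * 86400 + 13.5 * 3600
  s <- make_stream(offsets, rep(60, days), rep(0.06, days),
                   window = c(day0, day0 + days * 86400))
  segment_meals(s, cfg0)
}

test_that("28 all-nocturnal meals in 14 days give 2 meals/day, all nocturnal", {
  offsets <- as.vector(outer(c(13.5, 16) * 3600, (0:13) * 86400, "+"))
  s <- make_stream(sort(offsets), rep(60, 28), rep(0.06, 28), window = win14)
  summ <- summarize_microstructure(segment_meals(s, cfg0), bw_g = 30)
  get <- function(st, col) summ[[col]][summ$stratum == st]
  expect_equal(get("daily", "meal_count_per_day"), 2)
  expect_equal(get("nocturnal", "meal_count_per_day"), 2)
  expect_equal(get("diurnal", "meal_count_per_day"), 0)
  expect_equal(get("diurnal", "mean_meal_size_kcal"), NA_real_)
})

test_that("intake normalization: 12 kCal/day at 30 g is 0.4 kCal/gBW/day", {
  # 4 g/day in one nocturnal meal = 12 kCal/day
  offsets <- (0:13) * 86400 + 13 * 3600
  s <- make_stream(offsets, rep(600, 14), rep(4, 14), window = win14)
  summ <- summarize_microstructure(segment_meals(s, cfg0), bw_g = 30)
  daily <- summ[summ$stratum == "daily", ]
  expect_equal(daily$intake_kcal_per_day, 12)
  expect_equal(daily$intake_kcal_per_gbw_per_day, 0.4)
})

test_that("counts and intake are additive across photoperiod strata", {
  set.seed(33)
  sim <- simulate_cohort(generator_spec(seed = 33, n_animals = 2, days = 4),
                         cfg0)
  for (id in names(sim$streams)) {
    ms <- segment_meals(sim$streams[[id]], cfg0)
    summ <- summarize_microstructure(ms, animal = sim$animals[[id]])
    g <- function(st, col) summ[[col]][summ$stratum == st]
    expect_equal(g("daily", "n_meals"),
                 g("diurnal", "n_meals") + g("nocturnal", "n_meals"))
    expect_equal(g("daily", "intake_kcal"),
                 g("diurnal", "intake_kcal") + g("nocturnal", "intake_kcal"))
    # BW normalization is exact by construction
    expect_equal(g("daily", "intake_kcal_per_gbw_per_day") *
                   g("daily", "mean_bw_g"),
                 g("daily", "intake_kcal_per_day"))
  }
})

test_that("scaling all body weights by c scales intake/gBW by 1/c exactly", {
  ms <- nightly_series()
  s1 <- summarize_microstructure(ms, bw_g = 25)
  s2 <- summarize_microstructure(ms, bw_g = 50)
  expect_equal(s1$intake_kcal_per_gbw_per_day,
               2 * s2$intake_kcal_per_gbw_per_day)
})

test_that("summarize pools sub-windows consistently with the full window", {
  set.seed(5)
  sim <- simulate_cohort(generator_spec(seed = 5, n_animals = 1, days = 4),
                         cfg0)
  ms <- segment_meals(sim$streams[[1]], cfg0)
  full <- summarize_microstructure(ms, bw_g = 30)
  mid <- ms$window[1] + 2 * 86400
  h1 <- summarize_microstructure(ms, bw_g = 30, window = c(ms$window[1], mid))
  h2 <- summarize_microstructure(ms, bw_g = 30, window = c(mid, ms$window[2]))
  for (st in c("diurnal", "nocturnal", "daily")) {
    f <- full[full$stratum == st, ]
    a <- h1[h1$stratum == st, ]
    b <- h2[h2$stratum == st, ]
    expect_equal(f$n_meals, a$n_meals + b$n_meals)
    expect_equal(f$intake_kcal, a$intake_kcal + b$intake_kcal)
    # day-weighted pooling of per-day rates
    expect_equal(f$meal_count_per_day,
                 (a$meal_count_per_day * a$n_days +
                    b$meal_count_per_day * b$n_days) / (a$n_days + b$n_days))
  }
})

test_that("circadian profile puts isolated intake in its zeitgeber bin", {
  # single bout at zeitgeber 13.5 (= 20:00 clock)
  s <- make_stream(13.5 * 3600, 60, 0.5,
                   window = c(day0, day0 + 86400))
  prof <- circadian_profile(s, cfg0, bin_width_h = 1, bw_g = 25)
  expect_equal(sum(prof$intake_kcal > 0), 1)
  expect_equal(prof$zt_bin_start[prof$intake_kcal > 0], 13)
  expect_equal(prof$intake_kcal[prof$zt_bin_start == 13], 1.5)
  expect_equal(prof$intake_kcal_per_gbw[prof$zt_bin_start == 13], 1.5 / 25)
  expect_error(circadian_profile(s, cfg0, bin_width_h = 5), "divide 24")
})

test_that("the circadian profile integrates back to the total intake", {
  set.seed(12)
  sim <- simulate_cohort(generator_spec(seed = 12, n_animals = 1, days = 3),
                         cfg0)
  s <- sim$streams[[1]]
  prof <- circadian_profile(s, cfg0, bin_width_h = 2, bw_g = 30)
  total <- sum(prof$intake_kcal * prof$days_observed)
  expect_equal(total, sum(s$bouts$mass_g) * cfg0$energy_density_kcal_g)
  ms <- segment_meals(s, cfg0)
  summ <- summarize_microstructure(ms, bw_g = 30)
  expect_equal(total, summ$intake_kcal[summ$stratum == "daily"])
})

test_that("partial days weight circadian bins by observed time", {
  # 36-h window starting at lights-on: bins in [0,12) observed twice
  s <- make_stream(c(3600, 3600 + 86400), c(60, 60), c(0.1, 0.1),
                   window = c(day0, day0 + 36 * 3600))
  prof <- circadian_profile(s, cfg0, bin_width_h = 1, bw_g = 30)
  expect_equal(prof$days_observed[prof$zt_bin_start == 1], 2)
  expect_equal(prof$days_observed[prof$zt_bin_start == 13], 1)
  # the twice-observed 0.1-g bin averages to one bout per day
  expect_equal(prof$intake_kcal[prof$zt_bin_start == 1], 0.1 * 3)
})

test_that("cumulative intake is the running-sum step function", {
  s <- make_stream(c(0, 1000), c(60, 60), c(1 / 6, 1 / 6),
                   window = c(day0, day0 + 86400))
  cum <- cumulative_intake(s, cfg0)
  expect_equal(cum$cumulative_kcal, c(0, 0.5, 1.0))
  expect_true(all(diff(cum$cumulative_kcal) >= 0))
  set.seed(77)
  r <- random_stream(50)
  cr <- cumulative_intake(r, cfg0)
  expect_equal(max(cr$cumulative_kcal),
               sum(r$bouts$mass_g) * cfg0$energy_density_kcal_g)
  expect_equal(diff(cr$cumulative_kcal)[-1],
               (r$bouts$mass_g * cfg0$energy_density_kcal_g)[-1])
})
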