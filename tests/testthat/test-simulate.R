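test_that("identical seeds give bit-identical cohorts; seeds differ otherwise", {
  spec <- generator_spec(seed = 17, n_animals = 2, days = 2)
  a <- simulate_cohort(spec, cfg0)
  b <- simulate_cohort(spec, cfg0)
  expect_identical(lapply(a$streams, `[[`, "bouts"),
                   lapply(b$streams, `[[`, "bouts"))
  expect_identical(a$truth$true_meals, b$truth$true_meals)
  c <- simulate_cohort(generator_spec(seed = 18, n_animals = 2, days = 2),
                       cfg0)
  expect_false(identical(a$streams[[1]]$bouts, c$streams[[1]]$bouts))
})

test_that("recoverable mode enforces the invariants segmentation assumes", {
  sim <- simulate_cohort(generator_spec(seed = 23, n_animals = 3, days = 3),
                         cfg0)
  tm <- sim$truth$true_meals
  expect_true(all(tm$mass_g >= cfg0$min_meal_mass_g))
  expect_true(all(sim$truth$true_imis$interval_s >= cfg0$imi_threshold_s))
  for (id in names(sim$streams)) {
    b <- sim$streams[[id]]$bouts
    # every within-meal gap below, and every between-cluster gap at or
    # above, the threshold
    cl <- cluster_bouts(sim$streams[[id]], cfg0)
    gaps <- as.numeric(b$t_start[-1]) -
      (as.numeric(b$t_start[-nrow(b)]) + b$duration_s[-nrow(b)])
    expect_true(all(gaps > 0))
  }
})

test_that("segmentation recovers the ground-truth meal table exactly", {
  sim <- simulate_cohort(generator_spec(seed = 29, n_animals = 2, days = 4),
                         cfg0)
  for (id in names(sim$streams)) {
    ms <- segment_meals(sim$streams[[id]], cfg0)
    tm <- sim$truth$true_meals[sim$truth$true_meals$animal_id == id, ]
    expect_equal(nrow(ms$meals), nrow(tm))
    expect_equal(ms$meals$mass_g, tm$mass_g, tolerance = 1e-9)
    expect_equal(ms$meals$size_kcal, tm$size_kcal, tolerance = 1e-9)
    expect_equal(as.numeric(ms$meals$t_first), as.numeric(tm$t_first),
                 tolerance = 1e-6)
    ti <- sim$truth$true_imis[sim$truth$true_imis$animal_id == id, ]
    expect_equal(ms$imis$interval_s, ti$interval_s, tolerance = 1e-6)
    # truth meal masses equal the sum of the bouts emitted for them
    expect_equal(sum(tm$mass_g),
                 sum(ms$meals$mass_g), tolerance = 1e-9)
  }
})

test_that("inconsistent recoverable specs are rejected", {
  expect_error(generator_spec(
    nocturnal = list(meal_size_mean_kcal = 0.10)), "recoverable")
  expect_error(generator_spec(nibble_mass_range_g = c(0.01, 0.06)),
               "nibble")
  expect_error(generator_spec(nocturnal = list(mean_imi_min = -5)),
               "positive")
  expect_silent(generator_spec(nocturnal = list(meal_size_mean_kcal = 0.10),
                               recoverable = FALSE))
})

test_that("nibbles stay subthreshold and do not perturb detected meals", {
  quiet <- generator_spec(seed = 41, n_animals = 1, days = 3,
                          nibble_rate_per_day = 0)
  noisy <- generator_spec(seed = 41, n_animals = 1, days = 3,
                          nibble_rate_per_day = 12)
  ms_q <- segment_meals(simulate_cohort(quiet, cfg0)$streams[[1]], cfg0)
  sim_n <- simulate_cohort(noisy, cfg0)
  ms_n <- segment_meals(sim_n$streams[[1]], cfg0)
  expect_equal(ms_n$meals$mass_g, ms_q$meals$mass_g, tolerance = 1e-9)
  expect_equal(ms_n$imis$interval_s, ms_q$imis$interval_s, tolerance = 1e-6)
  expect_gt(nrow(ms_n$subthreshold), 0)
  expect_true(all(ms_n$subthreshold$mass_g < cfg0$min_meal_mass_g))
})

test_that("the refeed scenario keeps the fast window bout-free", {
  spec <- generator_spec(seed = 43, n_animals = 2,
                         refeed = list(suppression = 0.7, recovery_h = 6,
                                       overshoot = 1.3))
  rf <- simulate_refeed(spec, cfg0)
  for (id in names(rf$streams)) {
    b <- rf$streams[[id]]$bouts
    in_fast <- b$t_start >= rf$truth$fast_time &
      b$t_start < rf$truth$refeed_time
    expect_equal(sum(in_fast), 0)
  }
  expect_error(simulate_refeed(generator_spec(seed = 1), cfg0),
               "refeed")
})

test_that("generated IMI and meal-size means converge to the spec values", {
  spec <- generator_spec(seed = 47, n_animals = 6, days = 10)
  sim <- simulate_cohort(spec, cfg0)
  ti <- sim$truth$true_imis
  noct <- ti$interval_s[ti$photoperiod == "nocturnal"] / 60
  se <- sd(noct) / sqrt(length(noct))
  expect_lt(abs(mean(noct) - spec$nocturnal$mean_imi_min), 4 * se)
  tm <- sim$truth$true_meals
  noct_sz <- tm$size_kcal[tm$photoperiod == "nocturnal"]
  se_sz <- sd(noct_sz) / sqrt(length(noct_sz))
  expect_lt(abs(mean(noct_sz) - spec$nocturnal$meal_size_mean_kcal),
            4 * se_sz)
})

test_that("cohort presets cover the genotype x age grid per sex", {
  pres <- cohort_presets("female", seed = 2, n_animals = 3, days = 1)
  expect_length(pres, 6)
  expect_setequal(
    names(pres),
    c(outer(c("control", "knockout"), c(10, 20, 30),
            function(g, a) paste0(g, "_", a, "wk"))))
  expect_true(all(vapply(pres, function(s) s$sex == "female", logical(1))))
  # reduced satiation in knockouts: larger nocturnal meals at every age
  for (a in c(10, 20, 30))
    expect_gt(pres[[paste0("knockout_", a, "wk")]]$nocturnal$meal_size_mean_kcal,
              pres[[paste0("control_", a, "wk")]]$nocturnal$meal_size_mean_kcal)
  # distinct seeds per cell
  expect_equal(anyDuplicated(vapply(pres, `[[`, integer(1), "seed")), 0L)
})
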