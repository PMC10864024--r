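step_bins <- function(rel, bin_h = 2, monitor_h = 24, scot_from = 10.5,
                      scot_to = 22.5) {
  edges <- seq(0, monitor_h, by = bin_h)
  tibble::tibble(
    bin_start_h = edges[-length(edges)],
    bin_end_h = edges[-1],
    relative_imi = rel,
    n_imi = ifelse(is.na(rel), 0L, 5L),
    scotophase_overlap_h = pmax(0, pmin(edges[-1], scot_to) -
                                  pmax(edges[-length(edges)], scot_from))
  )
}

test_that("body-weight loss percentage and pairing follow the fast protocol", {
  spec <- generator_spec(seed = 21, n_animals = 1,
                         refeed = list(suppression = 0.6, recovery_h = 6,
                                       overshoot = 1.3))
  rf <- simulate_refeed(spec, cfg0)
  prof <- analyze_refeeding(rf$streams[[1]], baseline = 70,
                            animal = rf$animals[[1]], cfg = cfg0)
  expect_equal(prof$bw_prefast_g, 30)
  expect_equal(prof$bw_postfast_g, 27)
  expect_equal(prof$bw_loss_pct, 10)
  expect_equal(prof$fast_violation_bouts, 0)
  expect_equal(as.numeric(difftime(prof$refeed_time, prof$fast_time,
                                   units = "hours")), 16)
  expect_true(all(diff(prof$intake_curve$cumulative_kcal) >= 0))
})

test_that("a flat relative profile classifies as a null response", {
  k <- classify_kinetics(step_bins(rep(1, 12)))
  expect_equal(k$initial_suppression, 0)
  expect_equal(k$recovery_time_h, 0)
  expect_false(k$overshoot)
})

test_that("a 0.4/1.0 step profile recovers at the 6-8 h transition", {
  rel <- c(0.4, 0.4, 0.4, rep(1, 9))
  k <- classify_kinetics(step_bins(rel))
  expect_equal(k$initial_suppression, 0.6)
  expect_equal(k$recovery_time_h, 8)
  expect_false(k$overshoot)
  # with a late scotophase rise the third component is detected
  rel2 <- c(0.4, 0.4, 0.4, rep(1, 6), 1.3, 1.3, 1.3)
  k2 <- classify_kinetics(step_bins(rel2))
  expect_true(k2$overshoot)
  expect_equal(k2$overshoot_magnitude, 1.3)
})

test_that("classification needs at least two informative bins", {
  expect_error(classify_kinetics(step_bins(rep(NA_real_, 12))),
               "all bins are missing")
  expect_error(classify_kinetics(step_bins(c(0.5, rep(NA_real_, 11)))),
               "at least 2")
})

test_that("randomized profiles match a brute-force bin-scan oracle", {
  set.seed(64)
  for (i in 1:200) {
    rel <- runif(12, 0.2, 1.6)
    rel[sample(12, sample(0:3, 1))] <- NA
    if (sum(!is.na(rel)) < 2) next
    tol <- runif(1, 0.05, 0.2)
    bins <- step_bins(rel)
    k <- classify_kinetics(bins, tolerance = tol)
    # oracle: scan bins left to right
    ok <- which(!is.na(rel))
    expect_equal(k$initial_suppression, max(0, 1 - rel[ok[1]]))
    rec <- which(!is.na(rel) & rel >= 1 - tol)
    expect_equal(k$recovery_time_h,
                 if (!length(rec)) NA_real_
                 else if (rec[1] == ok[1]) 0 else bins$bin_end_h[rec[1]])
    scot <- which(!is.na(rel) & bins$scotophase_overlap_h > 0)
    if (length(scot)) {
      over <- scot[rel[scot] > 1 + tol]
      expect_equal(k$overshoot, length(over) > 0)
      expect_equal(k$overshoot_magnitude,
                   if (length(over)) mean(rel[over]) else max(rel[scot]))
    }
  }
})

test_that("paired normalization cancels a common IMI scale factor", {
  spec <- generator_spec(seed = 31, n_animals = 1,
                         refeed = list(suppression = 0.5, recovery_h = 6,
                                       overshoot = 1.4))
  rf <- simulate_refeed(spec, cfg0)
  p1 <- analyze_refeeding(rf$streams[[1]], baseline = 70, cfg = cfg0)
  p2 <- analyze_refeeding(rf$streams[[1]], baseline = 140, cfg = cfg0)
  expect_equal(p1$bins$relative_imi, 2 * p2$bins$relative_imi)
  # and classification on relative bins is unchanged under that pairing:
  # scaling both the animal's IMIs and its baseline leaves relative fixed
  expect_equal(p1$bins$mean_imi_min, p2$bins$mean_imi_min)
})

test_that("IMIs are assigned to the 2-h bin containing the interval start", {
  # refeed at 08:00; meals at +30 min (ends 08:35) and +200 min: the
  # interval starts at 08:35 -> bin [0, 2)
  refeed <- ts0("2024-01-02 08:00:00")
  s <- make_stream(c(-16.5 * 3600, 30 * 60, 200 * 60), c(300, 300, 300),
                   c(0.06, 0.06, 0.06),
                   base = refeed,
                   window = c(refeed - 18 * 3600, refeed + 24 * 3600))
  prof <- analyze_refeeding(s, baseline = 70, cfg = cfg0)
  expect_equal(prof$bins$n_imi[1], 1)
  expect_equal(prof$bins$mean_imi_min[1], 200 - 35)
  expect_equal(sum(prof$bins$n_imi), 1)
  # the fast itself is never an IMI: the pre-fast bout does not pair
  # with the first refeed meal
  expect_equal(prof$fast_violation_bouts, 0)
})

test_that("bouts inside the declared fast window are reported", {
  refeed <- ts0("2024-01-02 08:00:00")
  s <- make_stream(c(-8 * 3600, 30 * 60, 200 * 60), c(300, 300, 300),
                   c(0.06, 0.06, 0.06), base = refeed,
                   window = c(refeed - 18 * 3600, refeed + 24 * 3600))
  expect_warning(prof <- analyze_refeeding(s, baseline = 70, cfg = cfg0),
                 "fast window")
  expect_equal(prof$fast_violation_bouts, 1)
})

test_that("pooled group curves average paired relative IMIs by interval count", {
  b1 <- step_bins(c(0.4, rep(1, 11)))
  b2 <- step_bins(c(0.8, rep(NA_real_, 11)))
  b2$n_imi <- ifelse(is.na(b2$relative_imi), 0L, 15L)
  pooled <- pool_refeeding_bins(list(b1, b2))
  expect_equal(pooled$relative_imi[1], (0.4 * 5 + 0.8 * 15) / 20)
  expect_equal(pooled$relative_imi[2], 1)
  expect_equal(pooled$n_animals[1], 2)
  expect_equal(pooled$n_animals[2], 1)
})
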