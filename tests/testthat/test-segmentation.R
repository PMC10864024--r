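test_that("the 5-min / 0.050-g / 3.0-kCal/g constants force the worked examples", {
  # two 0.03-g bouts 200 s apart (end-to-start): one qualifying cluster
  s <- make_stream(c(0, 210), c(10, 10), c(0.03, 0.03))
  cl <- cluster_bouts(s, cfg0)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$mass_g, 0.06)
  expect_true(cl$qualifies)
  expect_equal(cl$size_kcal, 0.18)
  expect_equal(cl$eating_time_s, 20)
  # same bouts 390 s apart: two clusters, neither qualifies
  s2 <- make_stream(c(0, 400), c(10, 10), c(0.03, 0.03))
  cl2 <- cluster_bouts(s2, cfg0)
  expect_equal(nrow(cl2), 2)
  expect_false(any(cl2$qualifies))
  # gap exactly at the threshold separates (5 min is the smallest
  # separating interval)
  s3 <- make_stream(c(0, 310), c(10, 10), c(0.03, 0.03))
  expect_equal(nrow(cluster_bouts(s3, cfg0)), 2)
})

test_that("degenerate streams segment cleanly", {
  empty <- bout_stream(tibble::tibble(t_start = ts0(character()),
                                      duration_s = numeric(),
                                      mass_g = numeric()), "m0")
  ms <- segment_meals(empty, cfg0)
  expect_equal(nrow(ms$meals), 0)
  expect_equal(nrow(ms$subthreshold), 0)
  expect_equal(nrow(ms$imis), 0)
  # a single isolated 0.049-g bout is subthreshold but its mass is kept
  s <- make_stream(0, 30, 0.049)
  ms2 <- segment_meals(s, cfg0)
  expect_equal(nrow(ms2$meals), 0)
  expect_equal(nrow(ms2$subthreshold), 1)
  expect_equal(sum(ms2$subthreshold$mass_g), 0.049)
})

test_that("IMIs run between qualifying meals; the worked 70-min interval", {
  # meal ending 19:00 (bout 18:55+300 s), next meal starting 20:10
  base <- ts0("2024-01-01 18:55:00")
  s <- make_stream(c(0, 75 * 60), c(300, 300), c(0.06, 0.06), base = base)
  ms <- segment_meals(s, cfg0)
  expect_equal(nrow(ms$meals), 2)
  expect_equal(ms$imis$interval_s, 70 * 60)
  expect_equal(ms$imis$photoperiod, "nocturnal")
})

test_that("subthreshold clusters are transparent for the IMI", {
  # meal, isolated 0.02-g nibble, meal: one IMI spanning meal to meal
  s <- make_stream(c(0, 2000, 4000), c(100, 10, 100),
                   c(0.06, 0.02, 0.06))
  ms <- segment_meals(s, cfg0)
  expect_equal(nrow(ms$meals), 2)
  expect_equal(nrow(ms$subthreshold), 1)
  expect_equal(ms$imis$interval_s, 4000 - 100)
  expect_true(all(ms$imis$interval_s >= cfg0$imi_threshold_s))
})

test_that("mass is conserved exactly across meals and subthreshold clusters", {
  set.seed(101)
  for (i in 1:20) {
    s <- random_stream(sample(5:80, 1))
    ms <- segment_meals(s, cfg0)
    expect_equal(sum(ms$meals$mass_g) + sum(ms$subthreshold$mass_g),
                 sum(s$bouts$mass_g), tolerance = 1e-12)
  }
})

test_that("threshold limits give one cluster per bout and one per stream", {
  set.seed(7)
  s <- random_stream(60)
  tiny <- protocol_config(imi_threshold_s = 1e-9)
  huge <- protocol_config(imi_threshold_s = 1e12)
  expect_equal(nrow(cluster_bouts(s, tiny)), nrow(s$bouts))
  expect_equal(nrow(cluster_bouts(s, huge)), 1)
})

test_that("cluster count is monotone non-increasing in the threshold", {
  set.seed(8)
  s <- random_stream(80)
  thresholds <- c(1, 10, 60, 120, 300, 600, 1800, 7200)
  counts <- vapply(thresholds, function(th)
    nrow(cluster_bouts(s, protocol_config(imi_threshold_s = th))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("with a minimum meal size, meal count can increase with the threshold", {
  # two adjacent 0.03-g bouts: separate (subthreshold) at a small
  # threshold, merged into one qualifying meal at a larger one
  s <- make_stream(c(0, 200), c(10, 10), c(0.03, 0.03))
  small <- protocol_config(imi_threshold_s = 60)
  expect_equal(nrow(segment_meals(s, small)$meals), 0)
  expect_equal(nrow(segment_meals(s, cfg0)$meals), 1)
})

test_that("linear-scan segmentation equals the brute-force pairwise oracle", {
  set.seed(2024)
  for (i in 1:60) {
    s <- random_stream(sample(2:60, 1))
    got <- cluster_bouts(s, cfg0)
    member <- integer(nrow(s$bouts))
    for (k in seq_len(nrow(got))) member[got$bout_indices[[k]]] <- k
    want <- oracle_partition(as.numeric(s$bouts$t_start),
                             s$bouts$duration_s, cfg0$imi_threshold_s)
    expect_identical(member, want)
  }
})

test_that("feeding rate divides size by eating time and guards zero duration", {
  m <- tibble::tibble(size_kcal = c(0.30, 0.2), eating_time_s = c(120, 0))
  expect_equal(feeding_rate(m), c(0.0025, NA_real_))
})

test_that("meal duration reporting mode switches between eating time and span", {
  s <- make_stream(c(0, 200), c(50, 50), c(0.04, 0.04))
  eat <- segment_meals(s, cfg0)
  expect_equal(eat$meals$duration_s, 100)
  span_cfg <- protocol_config(meal_duration_mode = "span")
  sp <- segment_meals(s, span_cfg)
  expect_equal(sp$meals$duration_s, 250)
  expect_true(all(eat$meals$eating_time_s <= eat$meals$span_s))
})
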