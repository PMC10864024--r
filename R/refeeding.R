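#' Fasting-refeeding satiety analysis
#'
#' Analyzes the 24 h of refeeding that follow an overnight fast: body
#' weight lost over the fast, meals re-segmented with the identical
#' operational definition used ad libitum, intermeal intervals pooled into
#' fixed bins (2 h by default) by the time the interval starts, and each
#' bin expressed relative to the animal's own ad libitum baseline IMI
#' (paired normalization — never a group baseline). The fast itself is
#' never counted as an intermeal interval, and the first post-refeed meal
#' has no preceding IMI.
#'
#' @param stream A [bout_stream()] covering the fast and the refeeding
#'   monitor window.
#' @param baseline The animal's ad libitum baseline: either a single
#'   numeric mean nocturnal IMI in minutes, or a
#'   [summarize_microstructure()] tibble from which the nocturnal
#'   `mean_imi_min` row is taken.
#' @param animal Optional [animal_record()] supplying body weights; the
#'   weights nearest to (within 1 h of) the fast start and refeed start are
#'   used as pre/post-fast body weight.
#' @param cfg A [protocol_config()]; supplies fast/refeed clock times, the
#'   monitor length and the bin width. Meals during refeeding are segmented
#'   with this same config.
#' @param refeed_time Optional `POSIXct` instant food was returned;
#'   defaults to the first occurrence of `cfg$refeed_start` at or after the
#'   stream window start plus, when needed, enough days for the monitor to
#'   fit the window.
#' @return An object of class `refeeding_profile`: a list with
#'   `animal_id`, `refeed_time`, `fast_time`, `bw_prefast_g`,
#'   `bw_postfast_g`, `bw_loss_pct`, `fast_violation_bouts` (bouts detected
#'   inside the declared fast window — a food-access error in the data),
#'   `baseline_imi_min`, `series` (the refeed `meal_series`),
#'   `meal_size_refeed_kcal`, `intake_curve` (cumulative kCal at bin
#'   edges), and `bins`: one row per bin with `bin_start_h`, `bin_end_h`,
#'   `mean_imi_min`, `n_imi`, `relative_imi` and `scotophase_overlap_h`.
#'   Bins with no interval are `NA` (missing, not zero).
#' @export
analyze_refeeding <- function(stream, baseline, animal = NULL, cfg,
                              refeed_time = NULL) {
  stopifnot(inherits(stream, "bout_stream"), inherits(cfg, "protocol_config"))
  baseline_imi <- baseline_imi_min(baseline)

  win <- stream$window
  if (anyNA(win)) stop("the refeeding stream needs a recording window.",
                       call. = FALSE)
  if (is.null(refeed_time)) {
    # latest refeed-clock instant whose whole monitor window fits the stream
    refeed_time <- prev_clock_time(win[2] - cfg$refeed_monitor_h * 3600,
                                   cfg$refeed_start_h)
    if (refeed_time < win[1])
      stop("no refeed start time with a complete ", cfg$refeed_monitor_h,
           "-h monitor window fits the stream; pass `refeed_time`.",
           call. = FALSE)
  }
  monitor_end <- refeed_time + cfg$refeed_monitor_h * 3600
  if (monitor_end > win[2] + 1e-6)
    stop("the stream window ends before refeed start + ",
         cfg$refeed_monitor_h, " h.", call. = FALSE)
  fast_time <- prev_clock_time(refeed_time, cfg$fast_start_h)

  b <- stream$bouts
  in_fast <- b$t_start >= fast_time & b$t_start < refeed_time
  n_viol <- sum(in_fast)
  if (n_viol > 0)
    warning(n_viol, " bout(s) recorded inside the declared fast window (",
            format(fast_time), " .. ", format(refeed_time),
            ") for animal ", stream$animal_id,
            ": food-access error in the data.", call. = FALSE)

  refeed_bouts <- b[b$t_start >= refeed_time & b$t_start < monitor_end, ,
                    drop = FALSE]
  refeed_stream <- bout_stream(refeed_bouts, stream$animal_id,
                               window = c(refeed_time, monitor_end))
  series <- segment_meals(refeed_stream, cfg)

  # body weight at fast start and refeed start (nearest within 1 h)
  bw_at <- function(t) {
    if (is.null(animal) || !nrow(animal$body_weight)) return(NA_real_)
    d <- abs(as.numeric(animal$body_weight$timestamp) - as.numeric(t))
    if (min(d) > 3600) return(NA_real_)
    animal$body_weight$bw_g[which.min(d)]
  }
  bw_pre <- bw_at(fast_time)
  bw_post <- bw_at(refeed_time)
  if (!is.null(animal) && (is.na(bw_pre) || is.na(bw_post)))
    warning("missing pre-fast or post-fast body weight for animal ",
            stream$animal_id, "; BW fields left NA.", call. = FALSE)
  bw_loss_pct <- 100 * (bw_pre - bw_post) / bw_pre

  n_bins <- as.integer(round(cfg$refeed_monitor_h / cfg$refeed_bin_h))
  edges <- seq(0, cfg$refeed_monitor_h, by = cfg$refeed_bin_h)
  imis <- series$imis
  if (nrow(imis)) {
    start_h <- as.numeric(series$meals$t_last[imis$meal_index] - refeed_time,
                          units = "secs") / 3600
    bin_of <- pmin(findInterval(start_h, edges), n_bins)
  } else {
    bin_of <- integer()
  }
  mean_imi <- rep(NA_real_, n_bins)
  n_imi <- integer(n_bins)
  for (k in seq_len(n_bins)) {
    sel <- bin_of == k
    n_imi[k] <- sum(sel)
    if (n_imi[k]) mean_imi[k] <- mean(imis$interval_s[sel]) / 60
  }
  scot <- vapply(seq_len(n_bins), function(k)
    scotophase_overlap_h(refeed_time, edges[k], edges[k + 1], cfg), numeric(1))
  bins <- tibble::tibble(
    bin_start_h = edges[-length(edges)],
    bin_end_h = edges[-1],
    mean_imi_min = mean_imi,
    n_imi = n_imi,
    relative_imi = mean_imi / baseline_imi,
    scotophase_overlap_h = scot
  )

  cum <- cumulative_intake(refeed_stream, cfg)
  curve_kcal <- vapply(edges, function(h) {
    upto <- cum$cumulative_kcal[cum$t <= refeed_time + h * 3600]
    if (length(upto)) upto[length(upto)] else 0
  }, numeric(1))
  intake_curve <- tibble::tibble(
    hours = edges, cumulative_kcal = curve_kcal,
    cumulative_kcal_per_gbw = curve_kcal / bw_post)

  structure(list(
    animal_id = stream$animal_id,
    refeed_time = refeed_time, fast_time = fast_time,
    bw_prefast_g = bw_pre, bw_postfast_g = bw_post,
    bw_loss_pct = bw_loss_pct,
    fast_violation_bouts = n_viol,
    baseline_imi_min = baseline_imi,
    series = series,
    meal_size_refeed_kcal = if (nrow(series$meals))
      mean(series$meals$size_kcal) else NA_real_,
    intake_curve = intake_curve,
    bins = bins
  ), class = "refeeding_profile")
}

baseline_imi_min <- function(baseline) {
  if (is.data.frame(baseline)) {
    row <- baseline[baseline$stratum == "nocturnal", , drop = FALSE]
    if (!nrow(row) || is.na(row$mean_imi_min[1]))
      stop("baseline summary has no defined nocturnal mean IMI.", call. = FALSE)
    baseline <- row$mean_imi_min[1]
  }
  baseline <- as.numeric(baseline)
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline IMI must be a positive number of minutes.", call. = FALSE)
  baseline
}

# first instant with the given clock time at or after `t`
next_clock_time <- function(t, clock_h) {
  ahead <- (clock_h - clock_hours(t)) %% 24
  t + ahead * 3600
}

# last instant with the given clock time at or before `t`
prev_clock_time <- function(t, clock_h) {
  behind <- (clock_hours(t) - clock_h) %% 24
  t - behind * 3600
}

# hours of [refeed + a, refeed + b) spent in the scotophase
scotophase_overlap_h <- function(refeed_time, a, b, cfg) {
  z0 <- zeitgeber_time(refeed_time, cfg)
  L <- photophase_length(cfg)
  hours_in_zt_bin(z0 + a, b - a, L, 24)
}

#' @export
print.refeeding_profile <- function(x, ...) {
  cat(sprintf("<refeeding_profile> animal %s: refeed %s, fast %s\n",
              x$animal_id, format(x$refeed_time), format(x$fast_time)))
  if (!is.na(x$bw_loss_pct))
    cat(sprintf("  BW %.1f g -> %.1f g (loss %.1f%%)\n",
                x$bw_prefast_g, x$bw_postfast_g, x$bw_loss_pct))
  cat(sprintf("  baseline IMI %.1f min; %d meals during refeeding; intake %.2f kCal\n",
              x$baseline_imi_min, nrow(x$series$meals),
              max(x$intake_curve$cumulative_kcal)))
  print(x$bins)
  invisible(x)
}

#' Pool refeeding profiles into a group relative-IMI curve
#'
#' Averages the paired (per-animal, self-baseline-normalized) relative
#' IMIs across animals, bin by bin, weighting each animal's bin by its
#' number of intervals. Bins with no interval in any animal stay missing.
#' The pooled curve is what group-level kinetics are classified on.
#'
#' @param profiles A list of [analyze_refeeding()] results (or of their
#'   `bins` tibbles).
#' @return A tibble shaped like a profile's `bins`: `bin_start_h`,
#'   `bin_end_h`, `relative_imi` (pooled), `n_imi` (total),
#'   `n_animals` (contributing), `scotophase_overlap_h`.
#' @export
pool_refeeding_bins <- function(profiles) {
  bins_list <- lapply(profiles, function(p)
    if (inherits(p, "refeeding_profile")) p$bins else tibble::as_tibble(p))
  ref <- bins_list[[1]]
  for (b in bins_list[-1])
    if (!identical(b$bin_start_h, ref$bin_start_h))
      stop("profiles have different bin grids and cannot be pooled.",
           call. = FALSE)
  nb <- nrow(ref)
  rel <- sapply(bins_list, `[[`, "relative_imi")
  n <- sapply(bins_list, `[[`, "n_imi")
  rel <- matrix(rel, nrow = nb)
  n <- matrix(n, nrow = nb)
  w <- ifelse(is.na(rel), 0, n)
  tot <- rowSums(w)
  pooled <- ifelse(tot > 0, rowSums(ifelse(is.na(rel), 0, rel * w)) /
                     pmax(tot, 1), NA_real_)
  tibble::tibble(
    bin_start_h = ref$bin_start_h,
    bin_end_h = ref$bin_end_h,
    relative_imi = pooled,
    n_imi = as.integer(tot),
    n_animals = rowSums(w > 0),
    scotophase_overlap_h = ref$scotophase_overlap_h
  )
}

#' Classify fasting-induced satiety kinetics
#'
#' Reduces a binned relative-IMI profile to the three components of the
#' satiety response to refeeding: (1) initial suppression of the intermeal
#' interval (shortened satiety immediately after food return), (2) the time
#' at which the interval recovers to the ad libitum baseline, and (3) a
#' late overshoot above baseline in the scotophase (prolonged satiety at
#' the end of the dark phase). Deterministic given the profile and
#' tolerance.
#'
#' @param profile A [analyze_refeeding()] result, or a tibble shaped like
#'   its `bins` element.
#' @param tolerance Recovery/overshoot band as a fraction of baseline: a
#'   bin counts as recovered when `relative_imi >= 1 - tolerance`, and as
#'   overshooting when `relative_imi > 1 + tolerance`. Default 0.1.
#' @return An object of class `satiety_kinetics`: a list with
#'   `initial_suppression` (`1 - relative_imi` of the first informative
#'   bin, floored at 0), `first_bin_relative`, `recovery_time_h` (0 when
#'   the first informative bin is already at baseline; otherwise the right
#'   edge of the first recovered bin; `NA` if never recovered), `overshoot`
#'   (logical, scotophase bins only), `overshoot_magnitude` (mean relative
#'   IMI over the overshooting scotophase bins, or the scotophase maximum
#'   when none exceeds the band) and `tolerance`.
#' @export
classify_kinetics <- function(profile, tolerance = 0.1) {
  bins <- if (inherits(profile, "refeeding_profile")) profile$bins else
    tibble::as_tibble(profile)
  stopifnot(all(c("bin_start_h", "bin_end_h", "relative_imi") %in% names(bins)))
  if (!"scotophase_overlap_h" %in% names(bins))
    bins$scotophase_overlap_h <- 0
  ok <- which(!is.na(bins$relative_imi))
  if (!length(ok))
    stop("all bins are missing: no intermeal interval to classify.",
         call. = FALSE)
  if (length(ok) < 2)
    stop("need at least 2 non-missing bins to classify kinetics.",
         call. = FALSE)
  first <- ok[1]
  first_rel <- bins$relative_imi[first]
  suppression <- max(0, 1 - first_rel)
  recovered <- !is.na(bins$relative_imi) & bins$relative_imi >= 1 - tolerance
  rec_idx <- which(recovered)
  recovery_time <- if (!length(rec_idx)) NA_real_
    else if (rec_idx[1] == first) 0
    else bins$bin_end_h[rec_idx[1]]
  scot <- !is.na(bins$relative_imi) & bins$scotophase_overlap_h > 0
  over <- scot & bins$relative_imi > 1 + tolerance
  # magnitude averages the overshooting bins (a max over noisy bins is
  # upward-biased); with no bin above the band it reports the scotophase
  # maximum so a near-miss is still visible
  over_mag <- if (any(over)) mean(bins$relative_imi[over])
    else if (any(scot)) max(bins$relative_imi[scot]) else NA_real_
  structure(list(
    initial_suppression = suppression,
    first_bin_relative = first_rel,
    recovery_time_h = recovery_time,
    overshoot = any(over),
    overshoot_magnitude = over_mag,
    tolerance = tolerance
  ), class = "satiety_kinetics")
}

#' @export
print.satiety_kinetics <- function(x, ...) {
  cat("<satiety_kinetics>\n")
  cat(sprintf("  initial suppression: %.2f (first-bin relative IMI %.2f)\n",
              x$initial_suppression, x$first_bin_relative))
  cat(sprintf("  recovery time      : %s h\n",
              ifelse(is.na(x$recovery_time_h), "not reached",
                     format(x$recovery_time_h))))
  cat(sprintf("  scotophase overshoot: %s (relative IMI %.2f)\n",
              ifelse(x$overshoot, "yes", "no"), x$overshoot_magnitude))
  invisible(x)
}
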