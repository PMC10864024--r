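---
title: "Feeding microstructure: meal segmentation, satiation and satiety metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feeding microstructure: meal segmentation, satiation and satiety metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealscan)
```

## The measurement problem

Home-cage feeding monitors record *bouts*: individual feeder visits with a
start time, a duration and the mass of food removed. Behavioral questions,
however, are posed at the level of *meals*. Two distinct physiological
processes shape the meal pattern: **satiation**, the processes that
terminate an ongoing meal, read out as meal size (kCal); and **satiety**,
the processes that defer the next meal, read out as the intermeal interval
(IMI). A change in daily intake can come from either margin, and animals
with identical daily intake can differ radically in how they structure it.
`mealscan` turns raw bout streams into those readouts, with an explicit,
configurable operational meal definition.

## The operational meal definition

Two constants define a meal, both stored in a `protocol_config`:

* **IMI threshold** (`imi_threshold_s`, default 300 s): consecutive bouts
  whose end-to-start gap is *below* the threshold belong to the same
  cluster; a gap at or above it separates clusters. Five minutes is the
  conventional criterion for mice on chow; it is the smallest interval
  treated as a genuine between-meal pause rather than a pause within one
  meal.
* **Minimum meal size** (`min_meal_mass_g`, default 0.050 g): a cluster
  qualifies as a meal only when its total mass reaches this floor. Smaller
  clusters are *subthreshold* — kept, because the food they remove is
  still eaten (mass is conserved exactly: meal mass + subthreshold mass =
  total bout mass), but excluded from meal-based metrics.

Energy is mass × `energy_density_kcal_g` (default 3.0 kCal/g, standard
chow). No maximum meal size is imposed. All internal energy bookkeeping is
in kCal; some instruments and reports label intake axes "Cal" where kCal
is meant, and we deliberately do not apply any 1000× conversion anywhere.

Decisions that the definition leaves open, and what this package does:

* **Gap convention.** Gaps are measured end-to-start
  (`t_start[i+1] − (t_start[i] + duration[i])`), so time spent eating
  never counts toward an interval. Start-to-start gaps would conflate
  long bouts with short pauses.
* **Boundary.** `gap < threshold` joins; `gap ≥ threshold` separates —
  the threshold is the smallest *separating* interval.
* **IMI transparency.** The IMI runs from the end of one qualifying meal
  to the start of the next qualifying meal. A subthreshold nibble between
  two meals does not reset the interval. The alternative — censoring
  interrupted intervals — would discard most long intervals in nibbling
  animals and bias the satiety readout; transparency keeps the IMI
  interpretable as "time since the last meal". Every reported IMI is
  therefore ≥ the threshold by construction.
* **Meal duration.** "Time spent eating a meal" is ambiguous between the
  cluster span (first bout start to last bout end) and the summed bout
  durations. Both are computed; `meal_duration_mode` selects the
  reporting default (`eating_time`, the summed durations, since pauses
  within a meal are not eating).
* **Photoperiod of a meal.** A meal carries the photoperiod of its first
  bout and is never split at a light transition, which keeps counts
  additive across strata. Light transitions use half-open intervals
  `[lights_on, lights_off)`, so the two photoperiods tile the day exactly
  and every instant has one label. Days for per-day rates start at
  lights-on (zeitgeber time 0), matching the circadian axis.

## Summary metrics

`summarize_microstructure()` reports, per animal and per stratum
(diurnal / nocturnal / daily): meal frequency (meals/day, calendar-day
averaged over the window), mean meal size (kCal), mean IMI (min; each
interval assigned to the photoperiod in which it starts), mean meal
duration (s), mean feeding rate (meal size / meal duration, kCal/s; meals
with zero eating time are excluded rather than producing infinities), and
intake in kCal/day and kCal/gBW/day using the window-mean body weight.
Strata with zero meals report missing means, not zeros, so they cannot
bias group averages of per-meal quantities. `circadian_profile()`
accumulates all bouts (nibbles included) into zeitgeber-time bins,
weighting each bin by the time it was actually observed, so partial first
or last days do not distort the profile.

## Fasting–refeeding satiety kinetics

The fasting protocol removes food at 16:00 and returns it at 08:00 (a
16-h fast spanning the whole dark phase), then monitors 24 h of
refeeding. `analyze_refeeding()` re-segments the refeed day with the
*identical* config, pools IMIs into 2-h bins by the time each interval
starts, and divides each bin by the animal's own ad libitum nocturnal
mean IMI — a paired normalization; group baselines are never used. The
fast itself is never counted as an interval, and the first post-refeed
meal has no preceding IMI. Bouts detected inside the declared fast window
are reported as food-access errors, not silently analyzed.

`classify_kinetics()` reduces the binned relative curve to three
components: initial suppression (1 − relative IMI of the first
informative bin — fasted mice eat again much sooner than baseline),
recovery time (right edge of the first bin whose relative IMI is within
`tolerance` of baseline; 0 when already at baseline), and a late
scotophase overshoot (relative IMI above `1 + tolerance` in bins
overlapping the dark phase; its magnitude is the mean over the
overshooting bins — a maximum over noisy bins would be upward-biased).
The default tolerance of 0.1 suits smooth group curves; when classifying
pooled curves built from few intervals per bin a wider tolerance (0.2)
avoids flagging sampling noise as delayed recovery. Per-animal curves are
pooled with `pool_refeeding_bins()`, which weights each animal's bin by
its interval count.

## The synthetic generator

No raw bout streams ship with the package; `simulate_cohort()` generates
them with full ground truth, so every pipeline stage is testable. The
process is an alternating renewal: draw an IMI from a photoperiod-specific
gamma distribution, then emit a meal — gamma-distributed caloric size
(conditioned on the photoperiod the meal *starts* in, the same label the
analysis will assign), 1 + Poisson bouts, bout masses as normalized
uniform shares, within-meal gaps truncated-exponential below the
threshold, bout durations set by a fixed intake rate. Isolated
subthreshold nibbles are superposed at a Poisson rate. Distribution
families are chosen for positivity and tractable means; the instrument
literature specifies none.

Defaults emulate ad libitum chow feeding in adult mice: nocturnal mean
IMI 70 min (the established scale for this protocol), nocturnal meals of
0.55 kCal and diurnal meals of 0.40 kCal (meal sizes in the 0.5–0.7 kCal
range reported for adult mice), intake rate 0.0017 kCal/s (≈ 5-min meals),
2.0 extra bouts per meal on average, 30-s within-meal gaps, 5 nibbles/day.
There is no published diurnal IMI scale; the 180-min default is
*unanchored* and was chosen so that total daily frequency lands in the
13–16 meals/day range reported for these cohorts. The circadian structure
is two parameter sets, not a continuous oscillator, matching two-stratum
reporting. Body weight is bookkeeping (linear drift, fractional fast
loss, linear regain), not an energy-balance model.

In **recoverable mode** (the default) the generator enforces exactly the
invariants the meal definition assumes — between-meal gaps ≥ threshold,
within-meal gaps < threshold, meal masses ≥ the minimum, nibbles isolated
from meals by at least the threshold — so segmentation must reproduce the
truth table *exactly*, and the tests assert that it does (counts, masses
to 10⁻⁹ g, IMI sequences). Real streams honor no such guarantees:
passing these tests shows the algorithm implements the definition
faithfully, not that the definition is unambiguous on boundary-straddling
real data. `simulate_refeed()` adds a scripted fast (constructively
bout-free) and multiplies post-refeed IMI draws by a three-component step
curve (suppression until the recovery hour, baseline until the overshoot
onset at 18 h, overshoot thereafter), recording the injected curve in the
truth so recovered kinetics can be scored against it.

## Statistics

`anova_with_posthoc()` applies the conventional battery for such designs:
one- or two-way ANOVA (interaction included by default for two factors,
with a switch), the Tukey–Kramer post hoc test (studentized range with
the harmonic adjustment for unequal group sizes, via `TukeyHSD`),
Shapiro–Wilk normality and pairwise variance-F screening (reported, never
used to switch methods silently), and a per-group Grubbs single-outlier
scan (one pass, no iterative stripping), with listwise dropping of
missing responses. `grubbs_test()` uses the closed-form t-based critical
value. Tests verify agreement with independently coded direct-formula
oracles to 10⁻⁸ and null calibration (flag rate and familywise error
≈ α) by simulation.

## Problem sizes and numerical choices

The test suite exercises: 1,000 random streams (≤ 200 bouts) against a
brute-force pairwise-gap oracle; exact recovery on a 6-animal × 14-day
nibbled cohort; parameter recovery on 10 animals × 14 days judged against
Monte-Carlo intervals (the frequency reference is the generator's own
truth from an independent 100-animal run, since a closed-form renewal
rate ignores photoperiod-transition carryover of a few percent); a
27-scenario kinetics grid (suppression 0.5/0.7/0.9 × recovery 4/6/8 h ×
overshoot 1.3/1.5/1.7, 32 animals pooled per scenario, recovery scored to
within one bin); and 5,000-replicate null calibrations. Numerical
tie-breaks worth knowing: a gap exactly at the threshold separates;
clusters at exactly 0.050 g qualify; degenerate zero-duration meals get a
missing feeding rate; zero-variance samples flag no Grubbs outlier; and
in recoverable mode drawn quantities are clamped (not redrawn) at their
bounds, keeping the draw count — and hence reproducibility — independent
of parameter values.

## Limitations

The generator makes no mechanistic claims: no hormone dynamics, no
energy-balance coupling between intake and body weight, no continuous
circadian oscillator, no cage-mate interference. The reader assumes
per-animal bout attribution (transponder-resolved); cage-level demixing
is out of scope, as are drinking analysis and sub-bout microstructure.
Group-level empirical values from real cohorts are used only as
qualitative calibration anchors for the presets, never asserted as
expected outputs.

## A minimal session

```{r, eval = FALSE}
cfg <- protocol_config()
sim <- simulate_cohort(generator_spec(seed = 1, n_animals = 10, days = 14), cfg)
series <- lapply(sim$streams, segment_meals, cfg = cfg)
summaries <- dplyr::bind_rows(Map(summarize_microstructure,
                                  series, animal = sim$animals))
subset(summaries, stratum == "nocturnal",
       c(animal_id, meal_count_per_day, mean_meal_size_kcal, mean_imi_min))
```
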