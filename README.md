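# mealscan

Meal pattern segmentation and feeding-microstructure analysis for
bout-level event streams from home-cage feeding monitors.

## The problem

Home-cage monitors log individual **bouts** — feeder visits with a
timestamp, a duration and the mass of food removed. The behaviorally
meaningful unit, however, is the **meal**, and the two physiological
controls of intake act at the meal level:

* **satiation** — the processes that terminate a meal — is read out as
  *meal size* (kCal);
* **satiety** — the processes that delay the next meal — is read out as
  the *intermeal interval* (IMI, min).

`mealscan` implements the standard operational definition for mice on
chow: consecutive bouts with end-to-start gaps **< 5 min** belong to one
cluster, and a cluster is a meal when its mass is **≥ 0.050 g**
(energy = mass × 3.0 kCal/g; no maximal meal size). IMIs run from the end
of one qualifying meal to the start of the next; subthreshold "nibble"
clusters neither make meals nor interrupt intervals, but their mass still
counts toward intake, so total mass is conserved exactly. Everything is
stratified by photoperiod (12:12 light cycle, lights on 06:30), binned on
a zeitgeber-time axis for circadian profiles, and — for fasting–refeeding
experiments (16-h fast, 16:00 → 08:00) — expressed relative to each
animal's own ad libitum baseline to quantify the three components of the
post-fast satiety response (initial IMI suppression, recovery time, late
scotophase overshoot).

Because instrument-level recordings are rarely shared, the package ships
a calibrated synthetic generator (`simulate_cohort()`,
`simulate_refeed()`): an alternating-renewal bout process with
photoperiod-specific gamma IMIs and meal sizes, plus full ground-truth
meal tables against which segmentation is scored *exactly*. A statistics
module covers the usual group battery (Shapiro–Wilk and F screening,
one/two-way ANOVA, Tukey–Kramer post hoc, Grubbs single-outlier tests).

## Worked example

```r
library(mealscan)
cfg <- protocol_config()   # 5-min IMI, 0.050 g, 3.0 kCal/g, 06:30/18:30
sim <- simulate_cohort(generator_spec(seed = 1, n_animals = 4, days = 14), cfg)
series <- segment_meals(sim$streams[["animal_01"]], cfg)
series
#> <meal_series> animal animal_01: 186 meals (95.37 kCal), 72 subthreshold clusters (1.724 g), 185 IMIs

summ <- summarize_microstructure(series, animal = sim$animals[["animal_01"]])
summ[, c("stratum", "meal_count_per_day", "mean_meal_size_kcal",
         "mean_imi_min", "intake_kcal_per_day", "intake_kcal_per_gbw_per_day")]
#>     stratum meal_count_per_day mean_meal_size_kcal mean_imi_min
#> 1   diurnal               4.50               0.409        167.8
#> 2 nocturnal               8.79               0.566         69.1
#> 3     daily              13.29               0.513        102.1
#>   intake_kcal_per_day intake_kcal_per_gbw_per_day
#> 1                1.99                      0.0656
#> 2                5.19                      0.1710
#> 3                7.18                      0.2366
```

Reading the output: this animal eats ~13 meals/day, two-thirds of them at
night; nocturnal meals are larger (0.57 vs 0.41 kCal — the satiation
readout) and come every ~69 min (the satiety readout, vs ~168 min by
day), for ~7.2 kCal/day ≈ 0.24 kCal per gram of body weight. The numbers
sit where ad libitum chow-fed adult mice sit.

`run_pipeline()` chains simulate/read → segment → summarize → stats and
writes `meals.csv`, `summary.csv`, `circadian.csv`, `stats.json` and a
config snapshot; `inst/cli/mealscan.R` exposes the same stages as shell
subcommands (`simulate`, `segment`, `summarize`, `refeed`, `stats`,
`run-all`). See `vignette("feeding-microstructure")` for the methods and
design decisions.

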