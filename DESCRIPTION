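Package: mealscan
Title: Meal Pattern Segmentation and Feeding Microstructure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments bout-level home-cage feeding-event streams into meals
    and intermeal intervals using an operational meal definition (minimum
    intermeal-interval threshold and minimum meal size), and derives the
    behavioral satiation and satiety metrics used in rodent feeding
    microstructure studies: meal size, meal frequency, intermeal interval,
    meal duration and feeding rate, stratified by photoperiod; circadian
    intake profiles on a zeitgeber-time axis; fasting-refeeding satiety
    kinetics (suppression, recovery, late overshoot of the intermeal
    interval relative to each animal's ad libitum baseline); a calibrated
    synthetic bout-stream generator with ground-truth meal tables; and the
    group-statistics battery (Shapiro-Wilk and F screening, one- and
    two-way ANOVA with Tukey-Kramer post hoc comparisons, Grubbs
    single-outlier detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
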