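#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test: the statistic is the largest absolute deviation
#' from the sample mean in units of the sample standard deviation
#' (`n - 1` denominator). The candidate is flagged when the statistic
#' exceeds the critical value
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}}
#'   \sqrt{\frac{t^2}{n - 2 + t^2}}, \quad t = t_{\alpha/(2n),\, n-2},}
#' the usual t-based closed form. At most one value is flagged per call —
#' no iterative stripping.
#'
#' @param x Numeric sample, `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @return A list with `G` (statistic), `critical`, `p_value`
#'   (t-approximation, clamped to `[0, 1]`), `outlier` (the flagged value
#'   or `NA`), `index` (its position in `x` or `NA`) and `flagged`
#'   (logical). A zero-variance sample flags nothing by definition.
#' @examples
#' grubbs_test(c(8, 9, 10, 50))$flagged  # TRUE
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (anyNA(x)) x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("Grubbs test needs at least 3 observations.", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0)
    return(list(G = 0, critical = grubbs_critical(n, alpha), p_value = 1,
                outlier = NA_real_, index = NA_integer_, flagged = FALSE))
  dev <- abs(x - mean(x)) / s
  i <- which.max(dev)
  G <- dev[i]
  crit <- grubbs_critical(n, alpha)
  # invert the critical-value relation to get a (conservative) p-value
  denom <- (n - 1)^2 - n * G^2
  p <- if (denom <= 0) 0 else {
    tstat <- sqrt(n * (n - 2) * G^2 / denom)
    min(1, 2 * n * stats::pt(tstat, n - 2, lower.tail = FALSE))
  }
  flagged <- G > crit
  list(G = unname(G), critical = crit, p_value = p,
       outlier = if (flagged) x[i] else NA_real_,
       index = if (flagged) i else NA_integer_,
       flagged = flagged)
}

grubbs_critical <- function(n, alpha) {
  t <- stats::qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' ANOVA with Tukey-Kramer post hoc and assumption screening
#'
#' The group-comparison battery applied to per-animal summary values:
#' Shapiro-Wilk normality per group and pairwise F tests of variance
#' homogeneity (reported as screening, never used to switch methods),
#' one-way or two-way ANOVA as dictated by the number of factors, the
#' Tukey-Kramer post hoc test (studentized-range comparisons with the
#' harmonic-mean adjustment for unequal group sizes, via
#' [stats::TukeyHSD()]), and a per-group Grubbs single-outlier scan.
#' Missing responses are dropped listwise.
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param factors Character vector of 1 or 2 factor column names.
#' @param alpha Significance level for flags (default 0.05).
#' @param interaction For two factors, include the interaction term
#'   (default `TRUE`).
#' @return An object of class `stats_report`: a list with `anova` (tibble
#'   `term, df, sum_sq, F, p`), `posthoc` (tibble `term, contrast, diff,
#'   lwr, upr, p_adj, significant`), `shapiro` (tibble `group, n, W, p`),
#'   `variance_f` (tibble `group_1, group_2, F, p`), `outliers` (tibble
#'   `group, n, G, critical, outlier, flagged`), plus `response`,
#'   `factors`, `alpha`, `n_used`, `n_dropped`.
#' @export
anova_with_posthoc <- function(data, response, factors, alpha = 0.05,
                               interaction = TRUE) {
  stopifnot(is.data.frame(data), length(factors) %in% 1:2)
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- data.frame(y = as.numeric(data[[response]]))
  for (f in factors) df[[f]] <- factor(data[[f]])
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  for (f in factors) {
    df[[f]] <- droplevels(df[[f]])
    if (nlevels(df[[f]]) < 2)
      stop("factor `", f, "` has fewer than 2 levels after dropping ",
           "missing values.", call. = FALSE)
  }
  if (length(factors) == 2) {
    cells <- table(df[[factors[1]]], df[[factors[2]]])
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)
      stop("empty cell(s) in the two-way design: ",
           paste(sprintf("%s:%s", rownames(cells)[empty[, 1]],
                         colnames(cells)[empty[, 2]]), collapse = ", "),
           call. = FALSE)
    }
    if (interaction && any(cells < 2))
      stop("two-way ANOVA with interaction needs at least 2 observations ",
           "per cell.", call. = FALSE)
  }
  grp <- interaction(df[factors], sep = ":", drop = TRUE)

  shapiro <- dplyr::bind_rows(lapply(levels(grp), function(g) {
    y <- df$y[grp == g]
    if (length(y) >= 3 && stats::sd(y) > 0) {
      sw <- stats::shapiro.test(y)
      tibble::tibble(group = g, n = length(y), W = unname(sw$statistic),
                     p = sw$p.value)
    } else {
      tibble::tibble(group = g, n = length(y), W = NA_real_, p = NA_real_)
    }
  }))

  pairs <- utils::combn(levels(grp), 2, simplify = FALSE)
  variance_f <- dplyr::bind_rows(lapply(pairs, function(pr) {
    y1 <- df$y[grp == pr[1]]; y2 <- df$y[grp == pr[2]]
    if (length(y1) >= 2 && length(y2) >= 2 && stats::sd(y1) > 0 &&
        stats::sd(y2) > 0) {
      vt <- stats::var.test(y1, y2)
      tibble::tibble(group_1 = pr[1], group_2 = pr[2],
                     F = unname(vt$statistic), p = vt$p.value)
    } else {
      tibble::tibble(group_1 = pr[1], group_2 = pr[2], F = NA_real_,
                     p = NA_real_)
    }
  }))

  rhs <- if (length(factors) == 1) factors else
    paste(factors[1], factors[2], sep = if (interaction) " * " else " + ")
  fit <- stats::aov(stats::as.formula(paste("y ~", rhs)), data = df)
  an <- stats::anova(fit)
  anova_tab <- tibble::tibble(
    term = trimws(rownames(an)), df = an$Df, sum_sq = an$`Sum Sq`,
    F = an$`F value`, p = an$`Pr(>F)`)
  anova_tab <- anova_tab[anova_tab$term != "Residuals", ]

  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)
  posthoc <- dplyr::bind_rows(lapply(names(tk), function(term) {
    m <- tk[[term]]
    tibble::tibble(term = term, contrast = rownames(m),
                   diff = unname(m[, "diff"]), lwr = unname(m[, "lwr"]),
                   upr = unname(m[, "upr"]), p_adj = unname(m[, "p adj"]),
                   significant = unname(m[, "p adj"] < alpha))
  }))

  outliers <- dplyr::bind_rows(lapply(levels(grp), function(g) {
    y <- df$y[grp == g]
    if (length(y) < 3)
      return(tibble::tibble(group = g, n = length(y), G = NA_real_,
                            critical = NA_real_, outlier = NA_real_,
                            flagged = FALSE))
    gt <- grubbs_test(y, alpha)
    tibble::tibble(group = g, n = length(y), G = gt$G,
                   critical = gt$critical, outlier = gt$outlier,
                   flagged = gt$flagged)
  }))

  structure(list(anova = anova_tab, posthoc = posthoc, shapiro = shapiro,
                 variance_f = variance_f, outliers = outliers,
                 response = response, factors = factors, alpha = alpha,
                 n_used = nrow(df), n_dropped = n_dropped),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> %s ~ %s (n = %d used, %d dropped; alpha = %g)\n",
              x$response, paste(x$factors, collapse = " x "), x$n_used,
              x$n_dropped, x$alpha))
  cat("ANOVA:\n"); print(as.data.frame(x$anova), row.names = FALSE)
  cat("Tukey-Kramer:\n"); print(as.data.frame(x$posthoc), row.names = FALSE)
  flg <- x$outliers[x$outliers$flagged, ]
  if (nrow(flg))
    cat("Grubbs outliers:", paste(sprintf("%s (%.3g)", flg$group,
                                          flg$outlier), collapse = ", "), "\n")
  invisible(x)
}

#' Write a stats report to CSV and JSON
#'
#' @param report A [anova_with_posthoc()] result.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_stats_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "stats_report"))
  if (!is.null(csv_path)) {
    tabs <- list(anova = report$anova, posthoc = report$posthoc,
                 shapiro = report$shapiro, variance_f = report$variance_f,
                 outliers = report$outliers)
    flat <- dplyr::bind_rows(lapply(names(tabs), function(nm) {
      t <- tabs[[nm]]
      t[] <- lapply(t, as.character)
      tibble::add_column(tidyr::pivot_longer(
        tibble::add_column(t, .row = seq_len(nrow(t))),
        -dplyr::all_of(".row"), names_to = "field", values_to = "value"),
        table = nm, .before = 1)
    }))
    utils::write.csv(flat, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(response = report$response, factors = report$factors,
           alpha = report$alpha, n_used = report$n_used,
           n_dropped = report$n_dropped, anova = report$anova,
           posthoc = report$posthoc, shapiro = report$shapiro,
           variance_f = report$variance_f, outliers = report$outliers),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
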