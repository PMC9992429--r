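#' Genetic gain by era regression
#'
#' Ordinary least squares of per-line breeding values (performance BLUPs or
#' genomic BLUPs) on the calendar year in which the lines were evaluated.
#' The slope is the annual genetic gain (t/ha per year); it is subjected to
#' a t-test for significance, and reported with both a t-quantile confidence
#' interval (the regression-standard interval for a slope) and percent gain
#' relative to the first-year mean. When a line was evaluated in several
#' years, its single value is dated to its *first* evaluation year by
#' default (`duplicates = "first"`), reflecting cohort entry; pass
#' pre-deduplicated data with `duplicates = "all"` to keep every record.
#'
#' @param values Tibble with columns `line`, `value` and `year` (calendar
#'   integers).
#' @param level Confidence level for the slope interval (default 0.95).
#' @param duplicates `"first"` (default) keeps each line's first year;
#'   `"all"` uses the rows as given.
#' @return An object of class `gain_estimate`: slope, intercept, slope SE,
#'   t statistic, df, p-value, CI bounds, percent gain per year, n, year
#'   range, and the regression data.
#' @export
estimate_genetic_gain <- function(values, level = 0.95,
                                  duplicates = c("first", "all")) {
  duplicates <- match.arg(duplicates)
  values <- as_tibble(values)
  if (!all(c("line", "value", "year") %in% names(values))) {
    abort("`values` needs columns line, value, year.")
  }
  if (duplicates == "first") {
    values <- values |>
      dplyr::group_by(.data$line) |>
      dplyr::arrange(.data$year, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  if (dplyr::n_distinct(values$year) < 2) {
    abort("Need at least 2 distinct years for era regression.")
  }
  if (nrow(values) < 3) abort("Need at least 3 lines.")

  x <- values$year; y <- values$value
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  df <- n - 2
  constant <- sd(y) < 1e-12
  se <- sqrt(sum(resid^2) / df / sxx)
  if (constant || se < 1e-300) {
    tstat <- NA_real_; pval <- NA_real_
  } else {
    tstat <- slope / se
    pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  }
  tq <- qt(1 - (1 - level) / 2, df)
  first_year_mean <- mean(y[x == min(x)])
  structure(list(
    slope = slope, intercept = intercept, se = se, statistic = tstat,
    df = df, p_value = pval, level = level,
    ci = c(lower = slope - tq * se, upper = slope + tq * se),
    pct_gain_per_year = 100 * slope / first_year_mean,
    n = n, year_range = range(x), constant = constant,
    data = values), class = "gain_estimate")
}

#' @export
print.gain_estimate <- function(x, ...) {
  cat(sprintf(
    "<gain_estimate> %.4f t/ha/yr (SE %.4f), %d lines, %d-%d\n  t = %s, p = %s, %d%% CI [%.4f, %.4f], %.2f%%/yr of first-year mean\n",
    x$slope, x$se, x$n, x$year_range[1], x$year_range[2],
    if (is.na(x$statistic)) "NA" else sprintf("%.2f", x$statistic),
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    round(100 * x$level), x$ci[1], x$ci[2], x$pct_gain_per_year))
  invisible(x)
}

#' @rdname estimate_genetic_gain
#' @param x A `gain_estimate`.
#' @param ... Unused.
#' @export
tidy.gain_estimate <- function(x, ...) {
  tibble(term = c("(Intercept)", "year"),
         estimate = c(x$intercept, x$slope),
         std_error = c(NA_real_, x$se),
         statistic = c(NA_real_, x$statistic),
         p_value = c(NA_real_, x$p_value))
}

#' @rdname estimate_genetic_gain
#' @export
glance.gain_estimate <- function(x, ...) {
  tibble(slope = x$slope, se = x$se, statistic = x$statistic, df = x$df,
         p_value = x$p_value, ci_lower = x$ci[1], ci_upper = x$ci[2],
         pct_gain_per_year = x$pct_gain_per_year, n = x$n,
         year_min = x$year_range[1], year_max = x$year_range[2])
}

#' Era-regression scatter with fitted trend
#'
#' @param object A `gain_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gain_estimate <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "red") +
    ggplot2::labs(
      x = "Trial year", y = "BLUP yield (t/ha)",
      title = sprintf("Genetic gain: %.4f t/ha per year (p %s)",
                      object$slope,
                      ifelse(is.na(object$p_value), "NA",
                             format.pval(object$p_value, digits = 2)))) +
    ggplot2::theme_minimal()
}

#' Normal-theory confidence interval of a mean
#'
#' The classic interval \eqn{\bar x \pm z^* \sigma/\sqrt n} with the
#' standard-normal quantile and the sample standard deviation — the form
#' used to band era-regression scatter plots. For the regression slope
#' itself, [estimate_genetic_gain()] reports the t-quantile interval; both
#' are labelled so consumers know which convention they hold.
#'
#' @param sample Numeric vector, length >= 2.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `mean`, `lower`, `upper`, `level`, `method` (`"z"`).
#' @export
confidence_interval <- function(sample, level = 0.95) {
  if (length(sample) < 2) abort("Need at least 2 observations.")
  check_range(level, "level", 1e-6, 1 - 1e-6)
  zq <- qnorm(1 - (1 - level) / 2)
  m <- mean(sample)
  half <- zq * sd(sample) / sqrt(length(sample))
  tibble(mean = m, lower = m - half, upper = m + half, level = level,
         method = "z")
}

#' Per-year cohort summary
#'
#' Counts and descriptive statistics of line values by trial year, in the
#' usual era-trial reporting format: n genotypes, n trials, n locations,
#' min, max, mean, SD and CV%.
#'
#' @param values Tibble `line`/`value`/`year`.
#' @param trials Optional plot-record tibble contributing per-year trial and
#'   location counts.
#' @return A tibble, one row per year.
#' @export
cohort_summary <- function(values, trials = NULL) {
  values <- as_tibble(values)
  base <- values |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_genotypes = dplyr::n_distinct(.data$line),
      min = min(.data$value), max = max(.data$value),
      mean = mean(.data$value), sd = sd(.data$value),
      .groups = "drop") |>
    dplyr::mutate(sd = ifelse(is.na(.data$sd), 0, .data$sd),
                  cv_pct = ifelse(.data$mean == 0, NA_real_,
                                  100 * .data$sd / .data$mean))
  if (!is.null(trials)) {
    meta <- as_tibble(trials) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(n_trials = dplyr::n_distinct(.data$trial),
                       n_locations = dplyr::n_distinct(.data$location),
                       .groups = "drop")
    base <- dplyr::left_join(base, meta, by = "year") |>
      dplyr::relocate("n_trials", "n_locations", .after = "n_genotypes")
  }
  base
}
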