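#' Binomial proportion with a Wald confidence interval
#'
#' Rate and normal-approximation (Wald) confidence interval for a count out
#' of a cohort, on the percent scale: `100 k/n +- z * 100 * sqrt(p(1-p)/n)`,
#' with `z` the standard-normal quantile at `(1 + conf_level)/2`. Bounds are
#' clamped to \[0, 100\]; at `k = 0` or `k = n` the Wald interval
#' degenerates to zero width, which is reported as-is (a known property of
#' the method, not an error).
#'
#' @param k Number of events (0 <= k <= n).
#' @param n Cohort size (>= 1).
#' @param conf_level Confidence level, default 0.95.
#' @return A `proportion_estimate` object: list with `k`, `n`, `rate`,
#'   `ci_low`, `ci_high` (all percent) and `conf_level`.
#' @examples
#' proportion_with_ci(63, 73)   # 86.30 [78.41, 94.19]
#' @export
proportion_with_ci <- function(k, n, conf_level = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > n) {
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  }
  if (conf_level <= 0 || conf_level >= 1) {
    stop("conf_level must be in (0, 1)", call. = FALSE)
  }
  p_hat <- k / n
  z <- stats::qnorm((1 + conf_level) / 2)
  half <- z * 100 * sqrt(p_hat * (1 - p_hat) / n)
  rate <- 100 * p_hat
  structure(
    list(k = k, n = n, rate = rate,
         ci_low = max(0, rate - half), ci_high = min(100, rate + half),
         conf_level = conf_level),
    class = "proportion_estimate"
  )
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.2f%% (%d%% Wald CI %.2f-%.2f)\n", x$k, x$n, x$rate,
              round(100 * x$conf_level), x$ci_low, x$ci_high))
  invisible(x)
}

#' Alarm and dystocia frequency table for a calving cohort
#'
#' One row per category — alarm, no alarm, and dystocia scores 0 through 4 —
#' each a [proportion_with_ci()] against the full cohort size, plus the
#' share of dystocia (scores 1-4) among alarmed deliveries, attached as the
#' `dystocia_share_alarmed` attribute (a `proportion_estimate`). A missing
#' score (`NA`) marks a delivery whose difficulty was not recorded — in the
#' field that is typically a missed alarm — and contributes to the cohort
#' denominator but to no score category.
#'
#' @param records Data frame with at least columns `alarm` (logical or 0/1)
#'   and `dystocia_score` (integer 0-4, `NA` if unrecorded).
#' @param conf_level Confidence level for the Wald intervals.
#' @return A `frequency_table` data frame with columns `category`, `k`, `n`,
#'   `rate`, `ci_low`, `ci_high`.
#' @export
frequency_table <- function(records, conf_level = 0.95) {
  if (!is.data.frame(records) || !nrow(records)) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("alarm", "dystocia_score") %in% names(records))) {
    stop("records needs columns 'alarm' and 'dystocia_score'", call. = FALSE)
  }
  alarm <- as.logical(records$alarm)
  score <- as.integer(records$dystocia_score)
  if (any(!is.na(score) & (score < 0L | score > 4L))) {
    stop("dystocia_score must be an integer in 0..4 (or NA if unrecorded)",
         call. = FALSE)
  }
  n <- nrow(records)
  cats <- c("alarm", "no alarm", paste("score", 0:4))
  ks <- c(sum(alarm), sum(!alarm),
          vapply(0:4, function(s) sum(score == s, na.rm = TRUE), integer(1)))
  rows <- lapply(seq_along(cats), function(i) {
    pe <- proportion_with_ci(ks[i], n, conf_level)
    data.frame(category = cats[i], k = pe$k, n = pe$n, rate = pe$rate,
               ci_low = pe$ci_low, ci_high = pe$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_alarm <- sum(alarm)
  if (n_alarm > 0) {
    attr(out, "dystocia_share_alarmed") <-
      proportion_with_ci(sum(alarm & !is.na(score) & score > 0L), n_alarm,
                         conf_level)
  }
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' @export
print.frequency_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$rate <- sprintf("%.2f", df$rate)
  df$ci_low <- sprintf("%.2f", df$ci_low)
  df$ci_high <- sprintf("%.2f", df$ci_high)
  print(df, row.names = FALSE)
  ds <- attr(x, "dystocia_share_alarmed")
  if (!is.null(ds)) {
    cat(sprintf("Dystocia among alarmed deliveries: %d/%d = %.1f%%\n",
                ds$k, ds$n, ds$rate))
  }
  invisible(x)
}

#' Summary statistics of a set of intervals
#'
#' Mean, sample standard deviation (n-1 denominator), quartiles (linear
#' interpolation, `stats::quantile` type 7), minimum and maximum. With a
#' single value the standard deviation is undefined; it is reported as 0
#' with `sd_undefined = TRUE`.
#'
#' @param values Numeric vector (minutes or days), length >= 1.
#' @param unit Unit label carried in the result (`"minutes"` or `"days"`).
#' @return An `interval_summary` object: list with `n`, `mean`, `sd`,
#'   `sd_undefined`, `q1`, `median`, `q3`, `min`, `max`, `unit`.
#' @examples
#' summarize_intervals(c(1, 2, 3, 4, 5))
#' @export
summarize_intervals <- function(values, unit = "minutes") {
  if (!is.numeric(values) || !length(values) || anyNA(values)) {
    stop("values must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  single <- length(values) == 1L
  structure(
    list(n = length(values), mean = mean(values),
         sd = if (single) 0 else stats::sd(values), sd_undefined = single,
         q1 = qs[1], median = qs[2], q3 = qs[3],
         min = min(values), max = max(values), unit = unit),
    class = "interval_summary"
  )
}

#' @export
print.interval_summary <- function(x, ...) {
  cat(sprintf(
    "n=%d  mean %.2f +- %.2f%s  Q1 %.1f  median %.1f  Q3 %.1f  range %.1f-%.1f (%s)\n",
    x$n, x$mean, x$sd, if (x$sd_undefined) " (sd undefined, n=1)" else "",
    x$q1, x$median, x$q3, x$min, x$max, x$unit))
  invisible(x)
}

ttest_result <- function(t, df, p, variant) {
  structure(list(t_statistic = t, degrees_of_freedom = df, p_value = p,
                 variant = variant),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t = %.4f, df = %.2f, p = %.4g\n",
              x$variant, x$t_statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Two-sample t-test for unpaired data
#'
#' `two_sample_ttest()` tests from raw values (delegating to
#' [stats::t.test()]); `two_sample_ttest_summary()` computes the identical
#' statistic in closed form from group sizes, means and standard deviations —
#' the form needed when only published summary statistics are available.
#' `"pooled"` uses the pooled variance with `n_a + n_b - 2` degrees of
#' freedom (the classical Student test); `"welch"` uses the
#' Welch-Satterthwaite approximation. P-values are two-sided.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param n_a,n_b Group sizes.
#' @param mean_a,mean_b Group means.
#' @param sd_a,sd_b Group sample standard deviations (>= 0).
#' @param variant `"pooled"` or `"welch"`.
#' @return A `ttest_result` object: `t_statistic`, `degrees_of_freedom`,
#'   `p_value`, `variant`.
#' @examples
#' # from published summaries: eutocia vs dystocia expulsion intervals
#' two_sample_ttest_summary(44, 56.9, 33.65, 19, 80.27, 29.8)
#' @export
two_sample_ttest <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  two_sample_ttest_summary(length(a), mean(a), stats::sd(a),
                           length(b), mean(b), stats::sd(b),
                           variant = variant, .raw = list(a = a, b = b))
}

#' @rdname two_sample_ttest
#' @export
two_sample_ttest_summary <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b,
                                     variant = c("pooled", "welch"),
                                     .raw = NULL) {
  variant <- match.arg(variant)
  if (n_a < 2L || n_b < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (sd_a < 0 || sd_b < 0) stop("standard deviations must be >= 0",
                                 call. = FALSE)
  if (sd_a == 0 && sd_b == 0 && mean_a == mean_b) {
    stop("both groups constant with equal means: t statistic undefined",
         call. = FALSE)
  }
  if (!is.null(.raw)) {
    # raw-data route: delegate to the reference implementation
    ht <- stats::t.test(.raw$a, .raw$b, var.equal = variant == "pooled")
    return(ttest_result(unname(ht$statistic), unname(ht$parameter),
                        ht$p.value, variant))
  }
  if (variant == "pooled") {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  ttest_result(t, df, 2 * stats::pt(-abs(t), df), variant)
}

#' Pearson chi-square test of frequencies
#'
#' For a matrix, tests independence of rows and columns (expected counts
#' from the margins); for a vector with null proportions `p`, tests
#' goodness of fit. No continuity correction is applied. Expected counts of
#' zero are an error.
#'
#' @param observed Non-negative integer counts: a matrix (2-way) or vector
#'   (1-way).
#' @param p Null proportions for the 1-way test (must sum to 1); defaults to
#'   uniform.
#' @return A `chisquare_result` object: `statistic`, `degrees_of_freedom`,
#'   `p_value`.
#' @examples
#' chi_square(matrix(c(10, 20, 20, 10), 2))
#' @export
chi_square <- function(observed, p = NULL) {
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers", call. = FALSE)
  }
  if (is.matrix(observed)) {
    expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
    if (any(expected == 0)) stop("expected cell count of zero",
                                 call. = FALSE)
    ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  } else {
    if (length(observed) < 2L) stop("need at least 2 categories",
                                    call. = FALSE)
    if (is.null(p)) p <- rep(1 / length(observed), length(observed))
    if (abs(sum(p) - 1) > 1e-9) stop("null proportions must sum to 1",
                                     call. = FALSE)
    if (any(p * sum(observed) == 0)) stop("expected cell count of zero",
                                          call. = FALSE)
    ht <- suppressWarnings(stats::chisq.test(observed, p = p))
  }
  structure(list(statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "chisquare_result")
}

#' @export
print.chisquare_result <- function(x, ...) {
  cat(sprintf("Chi-square test: X2 = %.4f, df = %g, p = %.4g\n",
              x$statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Circular time-of-day density of calving alerts
#'
#' Histogram density over the 24-hour clock (the density integrates to 1
#' over 24 hours) plus the shares of alerts in the windows 00:00-06:00 and
#' 22:00-06:00 (the latter wrapping midnight) — the night windows of
#' interest when assessing how often calvings would otherwise be missed.
#'
#' @param times Numeric clock times in decimal hours, each in \[0, 24).
#' @param bins Number of equal-width histogram bins (default 24).
#' @return An `alert_density` object: list with `density` (data frame:
#'   `bin_start`, `bin_end`, `count`, `density` per hour), `share_00_06`
#'   and `share_22_06` (percent), `n`.
#' @examples
#' alert_time_density(c(2, 3.5, 23, 14, 5))$share_22_06
#' @export
alert_time_density <- function(times, bins = 24L) {
  if (!length(times)) stop("no alert times supplied", call. = FALSE)
  if (any(is.na(times)) || any(times < 0 | times >= 24)) {
    stop("times must be in [0, 24)", call. = FALSE)
  }
  if (bins < 1L) stop("bins must be >= 1", call. = FALSE)
  breaks <- seq(0, 24, length.out = bins + 1L)
  idx <- findInterval(times, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = bins)
  width <- 24 / bins
  dens <- data.frame(bin_start = breaks[-length(breaks)],
                     bin_end = breaks[-1], count = counts,
                     density = counts / (length(times) * width))
  structure(
    list(density = dens,
         share_00_06 = 100 * mean(times < 6),
         share_22_06 = 100 * mean(times >= 22 | times < 6),
         n = length(times)),
    class = "alert_density"
  )
}

#' @export
print.alert_density <- function(x, ...) {
  cat(sprintf(
    "Alert time-of-day density (n = %d): %.1f%% in 00:00-06:00, %.1f%% in 22:00-06:00\n",
    x$n, x$share_00_06, x$share_22_06))
  invisible(x)
}

#' Total APGAR score of a neonate calf
#'
#' Sum of the five vitality components — mucous-membrane colour, heart rate,
#' muscle tone, activity and respiration — each scored 0 (absent/abnormal),
#' 1 (impaired) or 2 (normal), giving a total of 0-10. All arguments are
#' vectorized.
#'
#' @param mucous_membranes,heart_rate,muscle_tone,activity,respiration
#'   Integer scores in \{0, 1, 2\}.
#' @return Integer vector of totals in 0-10.
#' @examples
#' apgar_total(2, 2, 2, 2, 2)  # 10
#' @export
apgar_total <- function(mucous_membranes, heart_rate, muscle_tone, activity,
                        respiration) {
  comps <- list(mucous_membranes = mucous_membranes, heart_rate = heart_rate,
                muscle_tone = muscle_tone, activity = activity,
                respiration = respiration)
  for (nm in names(comps)) {
    v <- comps[[nm]]
    if (any(is.na(v)) || any(!v %in% c(0L, 1L, 2L))) {
      stop("APGAR component '", nm, "' must be 0, 1 or 2", call. = FALSE)
    }
  }
  as.integer(mucous_membranes + heart_rate + muscle_tone + activity +
               respiration)
}

#' Parse "mm:ss" durations into decimal minutes
#'
#' Published interval tables often print durations as minutes:seconds
#' (e.g. "80:16" = 80 min 16 s = 80.267 min). Plain numeric strings pass
#' through unchanged.
#'
#' @param x Character (or numeric) vector.
#' @return Numeric vector of decimal minutes.
#' @examples
#' parse_minutes(c("80:16", "56:54", "33"))
#' @export
parse_minutes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- vapply(as.character(x), function(s) {
    if (grepl("^\\s*\\d+:\\d{1,2}\\s*$", s)) {
      parts <- as.numeric(strsplit(trimws(s), ":", fixed = TRUE)[[1]])
      if (parts[2] >= 60) stop("seconds >= 60 in '", s, "'", call. = FALSE)
      parts[1] + parts[2] / 60
    } else if (grepl("^\\s*-?\\d*\\.?\\d+\\s*$", s)) {
      as.numeric(s)
    } else {
      stop("cannot parse duration '", s, "'", call. = FALSE)
    }
  }, numeric(1), USE.NAMES = FALSE)
  out
}
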