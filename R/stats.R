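# Two-arm trial statistics: unpooled Wald difference-in-proportions
# intervals, the 2x2 Pearson chi-square without continuity correction,
# Welch t contrasts, and two-proportion power / sample size.

check_counts <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive", call. = FALSE)
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    stop("event counts must satisfy 0 <= x <= n", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pearson chi-square test for a 2x2 table, no continuity correction
#'
#' The classic one-degree-of-freedom Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on the table of events and
#' non-events in two groups, with a two-sided p-value from the chi-square
#' distribution. No Yates correction is applied. Degenerate tables (the
#' event occurs never or always overall) return statistic 0 and p 1 with a
#' flag rather than 0/0.
#'
#' @param x1,n1 Events and size in group 1 (intervention).
#' @param x2,n2 Events and size in group 2 (control).
#' @return List with `statistic`, `p_value` and `degenerate`.
#' @examples
#' pearson_chi_square(64, 1062, 79, 1037)
#' @export
pearson_chi_square <- function(x1, n1, x2, n2) {
  check_counts(x1, n1, x2, n2)
  # double precision: margin products overflow integer range for large trials
  a <- as.numeric(x1); b <- as.numeric(n1 - x1)
  c <- as.numeric(x2); d <- as.numeric(n2 - x2)
  N <- n1 + n2
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  }
  stat <- N * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Difference in proportions with unpooled Wald interval
#'
#' The trial's effect estimate for binary outcomes: the difference in event
#' percentages between intervention (group 1) and control (group 2) with a
#' normal-approximation confidence interval using each group's own variance,
#' `diff +/- z * 100 * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`, plus the Pearson
#' chi-square test. All percentage-scale quantities are in percentage
#' points. When both observed proportions are 0 or 1 the Wald interval
#' degenerates to zero width; the result is flagged rather than replaced by
#' an alternative interval.
#'
#' @inheritParams pearson_chi_square
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `prop_comparison`; see [tidy.prop_comparison()].
#' @examples
#' proportion_difference(64, 1062, 79, 1037)
#' @export
proportion_difference <- function(x1, n1, x2, n2, conf_level = 0.95) {
  check_counts(x1, n1, x2, n2)
  stopifnot(conf_level > 0, conf_level < 1)
  p1 <- x1 / n1
  p2 <- x2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  chi <- pearson_chi_square(x1, n1, x2, n2)
  structure(list(
    x1 = x1, n1 = n1, x2 = x2, n2 = n2,
    p1_pct = 100 * p1, p2_pct = 100 * p2,
    diff_pct = 100 * (p1 - p2),
    ci_low_pct = 100 * (p1 - p2 - z * se),
    ci_high_pct = 100 * (p1 - p2 + z * se),
    chi2 = chi$statistic, p_value = chi$p_value,
    conf_level = conf_level,
    degenerate = chi$degenerate || se == 0
  ), class = "prop_comparison")
}

#' @export
print.prop_comparison <- function(x, ...) {
  cat(sprintf("Difference in proportions: %d/%d (%.1f%%) vs %d/%d (%.1f%%)\n",
              x$x1, x$n1, x$p1_pct, x$x2, x$n2, x$p2_pct))
  cat(sprintf("  diff %.2f pct points, %d%% CI (%.2f, %.2f)\n",
              x$diff_pct, round(100 * x$conf_level), x$ci_low_pct, x$ci_high_pct))
  cat(sprintf("  Pearson chi-square %.3f, p = %.4g%s\n", x$chi2, x$p_value,
              if (x$degenerate) " [degenerate table]" else ""))
  invisible(x)
}

#' Tidy a two-group comparison
#'
#' Broom-style one-row summaries. `tidy()` carries the counts, percentages,
#' difference, interval and test; `glance()` the estimate, interval and
#' p-value only.
#'
#' @param x A `prop_comparison` or `mean_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy prop_comparison
#' @export
tidy.prop_comparison <- function(x, ...) {
  tibble::tibble(
    x1 = x$x1, n1 = x$n1, p1_pct = x$p1_pct,
    x2 = x$x2, n2 = x$n2, p2_pct = x$p2_pct,
    diff_pct = x$diff_pct, ci_low_pct = x$ci_low_pct,
    ci_high_pct = x$ci_high_pct, chi2 = x$chi2, p_value = x$p_value,
    conf_level = x$conf_level, degenerate = x$degenerate
  )
}

#' @rdname tidy.prop_comparison
#' @method glance prop_comparison
#' @export
glance.prop_comparison <- function(x, ...) {
  tibble::tibble(estimate = x$diff_pct, conf.low = x$ci_low_pct,
                 conf.high = x$ci_high_pct, statistic = x$chi2,
                 p.value = x$p_value)
}

welch_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2, conf_level) {
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  diff <- mean1 - mean2
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  p <- if (se == 0) 1 else 2 * stats::pt(abs(diff) / se, df, lower.tail = FALSE)
  structure(list(mean1 = mean1, mean2 = mean2, sd1 = sd1, sd2 = sd2,
                 n1 = n1, n2 = n2, diff = diff,
                 ci_low = diff - tcrit * se, ci_high = diff + tcrit * se,
                 df = df, p_value = p, conf_level = conf_level),
            class = "mean_comparison")
}

#' Welch t contrast between two raw samples
#'
#' Mean difference (group 1 minus group 2) with an unequal-variance Welch
#' interval and two-sided p-value. Missing values are dropped, never
#' imputed; each group needs at least two non-missing observations.
#' [mean_difference_summary()] computes the same contrast from summary
#' statistics when raw values are unavailable.
#'
#' @param values1,values2 Numeric vectors of raw measurements.
#' @param conf_level Confidence level.
#' @return An object of class `mean_comparison`.
#' @export
mean_difference_raw <- function(values1, values2, conf_level = 0.95) {
  values1 <- values1[!is.na(values1)]
  values2 <- values2[!is.na(values2)]
  if (length(values1) < 2 || length(values2) < 2) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  tt <- stats::t.test(values1, values2, conf.level = conf_level, var.equal = FALSE)
  out <- welch_from_summaries(mean(values1), sd(values1), length(values1),
                              mean(values2), sd(values2), length(values2),
                              conf_level)
  # keep t.test's numbers as the source of truth
  out$ci_low <- tt$conf.int[1]
  out$ci_high <- tt$conf.int[2]
  out$p_value <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}

#' @rdname mean_difference_raw
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @export
mean_difference_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                    conf_level = 0.95) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  welch_from_summaries(mean1, sd1, n1, mean2, sd2, n2, conf_level)
}

#' @export
print.mean_comparison <- function(x, ...) {
  cat(sprintf("Mean difference: %.3f (%.1f +/- %.2f, n=%d vs %.1f +/- %.2f, n=%d)\n",
              x$diff, x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2))
  cat(sprintf("  %d%% CI (%.3f, %.3f), Welch df %.1f, p = %.4g\n",
              round(100 * x$conf_level), x$ci_low, x$ci_high, x$df, x$p_value))
  invisible(x)
}

#' @rdname tidy.prop_comparison
#' @method tidy mean_comparison
#' @export
tidy.mean_comparison <- function(x, ...) {
  tibble::tibble(mean1 = x$mean1, sd1 = x$sd1, n1 = x$n1,
                 mean2 = x$mean2, sd2 = x$sd2, n2 = x$n2,
                 diff = x$diff, ci_low = x$ci_low, ci_high = x$ci_high,
                 df = x$df, p_value = x$p_value, conf_level = x$conf_level)
}

#' @rdname tidy.prop_comparison
#' @method glance mean_comparison
#' @export
glance.mean_comparison <- function(x, ...) {
  tibble::tibble(estimate = x$diff, conf.low = x$ci_low, conf.high = x$ci_high,
                 p.value = x$p_value)
}

#' Power of the two-proportion z test
#'
#' Normal-approximation power to detect a difference between two independent
#' proportions. The default `"pooled"` method uses the pooled-proportion
#' standard error under the null (as the z test itself does) and the
#' unpooled standard error under the alternative — the classical
#' two-proportion z-test power formula; `"unpooled"` uses the unpooled
#' standard error in both places. Both tails of the two-sided rejection
#' region are counted, so `p1 = p2` returns the type-I error rate.
#'
#' @param p1,p2 True event probabilities in the two groups.
#' @param n1,n2 Group sizes (`n2` defaults to `n1`).
#' @param alpha Significance level.
#' @param sides 1 or 2 (two-sided by default).
#' @param method `"pooled"` (default) or `"unpooled"` null standard error.
#' @return Power as a probability.
#' @examples
#' two_proportion_power(0.075, 0.05, n1 = 1969)
#' @export
two_proportion_power <- function(p1, p2, n1, n2 = n1, alpha = 0.05, sides = 2,
                                 method = c("pooled", "unpooled")) {
  method <- match.arg(method)
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, alpha > 0, alpha < 1,
            n1 >= 2, n2 >= 2, sides %in% c(1, 2))
  delta <- abs(p1 - p2)
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  se0 <- if (method == "pooled") {
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  } else {
    se1
  }
  z <- qnorm(1 - alpha / sides)
  power <- pnorm((delta - z * se0) / se1)
  if (sides == 2) power <- power + pnorm((-delta - z * se0) / se1)
  unname(power)
}

#' Required per-group sample size for a two-proportion comparison
#'
#' The smallest equal per-group n whose [two_proportion_power()] reaches the
#' requested power for detecting `p_control` versus `p_control + delta`.
#' Uses the closed-form normal approximation as a starting point, then an
#' exact integer search against the power function, so the round trip
#' `two_proportion_power(required_n) >= power` always holds while `n - 1`
#' falls short.
#'
#' @param p_control Control-group event probability.
#' @param delta Absolute difference to detect (nonzero; intervention
#'   probability is `p_control + delta`).
#' @param alpha Significance level.
#' @param power Target power.
#' @inheritParams two_proportion_power
#' @return Integer per-group sample size.
#' @examples
#' required_n_per_group(0.05, 0.025)  # the 3938-participant planning scenario
#' @export
required_n_per_group <- function(p_control, delta, alpha = 0.05, power = 0.90,
                                 sides = 2, method = c("pooled", "unpooled")) {
  method <- match.arg(method)
  stopifnot(power > 0, power < 1)
  if (delta == 0) stop("delta must be nonzero", call. = FALSE)
  p1 <- p_control + delta
  if (p1 <= 0 || p1 >= 1) stop("p_control + delta must lie in (0, 1)", call. = FALSE)
  if (power <= alpha) return(2L)  # the test already rejects that often under the null
  za <- qnorm(1 - alpha / sides)
  zb <- qnorm(power)
  pbar <- (p_control + p1) / 2
  num <- if (method == "pooled") {
    (za * sqrt(2 * pbar * (1 - pbar)) +
       zb * sqrt(p1 * (1 - p1) + p_control * (1 - p_control)))^2
  } else {
    (za + zb)^2 * (p1 * (1 - p1) + p_control * (1 - p_control))
  }
  n <- max(2L, as.integer(floor(num / delta^2)) - 5L)
  pw <- function(n) two_proportion_power(p1, p_control, n1 = n, alpha = alpha,
                                         sides = sides, method = method)
  limit <- 1e9
  while (pw(n) < power) {
    n <- n + 1L
    if (n > limit) stop("requested power unreachable", call. = FALSE)
  }
  while (n > 2L && pw(n - 1L) >= power) n <- n - 1L
  n
}
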