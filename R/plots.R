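#' Forest plot of intention-to-treat outcome contrasts
#'
#' One row per binary outcome: the difference in percentages (intervention
#' minus control) with its Wald confidence interval, the null at zero dashed.
#'
#' @param table An `itt_table` from [itt_outcome_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_outcome_differences <- function(table, ...) {
  stopifnot(is.data.frame(table),
            all(c("outcome", "diff_pct", "ci_low_pct", "ci_high_pct") %in% names(table)))
  tab <- dplyr::mutate(table,
                       outcome = factor(.data$outcome, levels = rev(.data$outcome)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$diff_pct, y = .data$outcome)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low_pct,
                                         xmax = .data$ci_high_pct),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Difference, intervention - control (percentage points)",
                  y = NULL,
                  title = "Intention-to-treat outcome contrasts",
                  subtitle = sprintf("Unpooled Wald %d%% confidence intervals",
                                     round(100 * tab$conf_level[1]))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_outcome_differences
#' @param object An `itt_table`.
#' @importFrom ggplot2 autoplot
#' @method autoplot itt_table
#' @export
autoplot.itt_table <- function(object, ...) {
  plot_outcome_differences(object, ...)
}

#' Power curve for a two-proportion comparison
#'
#' Power of the two-proportion z test as a function of per-group sample
#' size, for a fixed control rate and detectable difference.
#'
#' @param p_control Control-group event probability.
#' @param delta Absolute difference to detect.
#' @param n_range Range of per-group sizes to plot.
#' @param alpha Significance level.
#' @param target Horizontal reference line (default 0.9).
#' @return A ggplot object.
#' @export
plot_power_curve <- function(p_control, delta, n_range = c(100, 4000),
                             alpha = 0.05, target = 0.9) {
  n <- seq(n_range[1], n_range[2], length.out = 200)
  dat <- tibble::tibble(
    n = n,
    power = vapply(n, function(nn)
      two_proportion_power(p_control + delta, p_control, n1 = nn, alpha = alpha),
      numeric(1)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Participants per group", y = "Power",
                  title = sprintf("Power to detect %+.1f points on %.1f%% (two-sided alpha %.2g)",
                                  100 * delta, 100 * p_control, alpha)) +
    ggplot2::theme_minimal()
}
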