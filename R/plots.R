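#' Plot a cohort trace
#'
#' State occupancy fractions over the model cycles.
#'
#' @param object A `cohort_trace` from [run_markov()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- as_tibble(object) %>%
    select("cycle", "remission", "t2dm", "dead") %>%
    tidyr::pivot_longer(-"cycle", names_to = "state", values_to = "fraction") %>%
    mutate(state = factor(.data$state, levels = c("remission", "t2dm", "dead")))
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$fraction, colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle (years)", y = "Occupancy fraction", colour = "State") +
    ggplot2::theme_minimal()
}

#' Plot cumulative discounted cost and QALYs for two strategies
#'
#' Mirrors the payback view of the base case: both strategies' cumulative
#' discounted cost (and, in the second panel, QALYs) by cycle, showing where
#' the up-front surgical cost is overtaken by medication maintenance costs.
#'
#' @param a,b `strategy_result` objects.
#' @return A ggplot object (two facets: cost and QALYs).
#' @export
plot_cumulative <- function(a, b) {
  long <- bind_rows(tidy(a), tidy(b)) %>%
    select("strategy", "cycle", cost = "cum_disc_cost", QALYs = "cum_disc_qaly") %>%
    tidyr::pivot_longer(c("cost", "QALYs"), names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$value, colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Cycle (years)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars span each parameter's incremental net monetary benefit
#' between its low and high bound; the dashed line marks the base case.
#'
#' @param object A `tornado` tibble from [one_way()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tornado <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(parameter = factor(.data$parameter, levels = rev(.data$parameter)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = pmin(.data$inmb_low, .data$inmb_high),
        xend = pmax(.data$inmb_low, .data$inmb_high),
        yend = .data$parameter
      ),
      linewidth = 5, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = attr(object, "base_inmb"), linetype = "dashed") +
    ggplot2::labs(x = "Incremental net monetary benefit (CNY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatter of the PSA draws
#'
#' Incremental QALYs against incremental cost per draw, with the
#' willingness-to-pay threshold drawn as a line through the origin.
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, ...) {
  d <- object$draws
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CNY)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param object A `ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (CNY/QALY)",
      y = "P(surgery cost-effective)"
    ) +
    ggplot2::theme_minimal()
}

#' Covariate balance (Love) plot
#'
#' Absolute standardized mean differences before and after matching, the
#' standard visual check that propensity matching balanced the arms.
#'
#' @param balance A [balance_report()] tibble.
#' @param threshold Reference line for acceptable imbalance (default 0.1).
#' @return A ggplot object.
#' @export
plot_balance <- function(balance, threshold = 0.1) {
  df <- as_tibble(balance) %>%
    filter(.data$type != "outcome") %>%
    mutate(phase = factor(.data$phase, levels = c("before", "after")))
  ggplot2::ggplot(df, ggplot2::aes(abs(.data$smd), .data$variable, colour = .data$phase)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dotted") +
    ggplot2::labs(x = "|Standardized mean difference|", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
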