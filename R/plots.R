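#' Plot methods for audit reports
#'
#' `autoplot()` methods give the standard diagnostic figures: stratified
#' observed-versus-programmed win rates, the balance trajectory against
#' its closed-form expectation, and the parallel-analysis scree.
#'
#' @param object A report object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name casinosim-plots
NULL

#' @rdname casinosim-plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mechanics_report <- function(object, ...) {
  strata <- tidy(object)
  ggplot2::ggplot(strata,
                  ggplot2::aes(x = .data$stratum, y = .data$observed_p)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$set_p), shape = 4,
                        size = 3, colour = "red") +
    ggplot2::facet_wrap(~ block_index, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(
      y = "win rate (dot: observed with 95% Wilson CI; cross: programmed)",
      x = NULL,
      title = "Observed vs programmed win rates"
    )
}

#' @rdname casinosim-plots
#' @export
autoplot.parallel_analysis <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series,
                              c("observed", "null_percentile"),
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component,
                                     y = .data$value,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "eigenvalue", x = "component",
                  title = "Parallel analysis scree")
}

#' @rdname casinosim-plots
#' @export
autoplot.quality_report <- function(object, ...) {
  ggplot2::ggplot(object$participants,
                  ggplot2::aes(x = .data$variation_score,
                               fill = .data$flagged)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(object$summary$lower,
                                       object$summary$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "response variation score (%)", y = "participants",
                  title = "Response-variation screening")
}

#' Plot a cohort's balance trajectory against the closed form
#'
#' @param analysis Result of [balance_trajectory_analysis()].
#' @return A ggplot object.
#' @export
plot_balance_trajectory <- function(analysis) {
  ggplot2::ggplot(analysis$by_trial,
                  ggplot2::aes(x = .data$trial_number)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed_mean_balance)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_balance),
                       linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "trial", y = "mean balance (credits)",
                  title = "Observed (solid) vs expected (dashed) balance")
}
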