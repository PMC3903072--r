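#' Plot posterior tumor ages
#'
#' Histogram of the per-sample posterior mean tumor age with the cohort
#' mean marked.
#'
#' @param object A `mutclock_posterior`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mutclock_posterior
#' @export
autoplot.mutclock_posterior <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$post_T)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(object$post_T),
                        linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "posterior mean tumor age (cell divisions)",
                  y = "samples") +
    ggplot2::theme_minimal()
}

#' Plot rate-increase estimates with bootstrap intervals
#'
#' One point range per driver: the estimated rate increase (as percent of
#' the baseline rate) with its percentile interval; drivers whose interval
#' excludes zero are the mutator calls.
#'
#' @param object A `mutclock_boot`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mutclock_boot
#' @export
autoplot.mutclock_boot <- function(object, ...) {
  lam <- object$fit$fixed$lam
  df <- object$delta_ci %>%
    dplyr::mutate(
      pct = 100 * .data$delta_hat / lam,
      pct_lo = 100 * .data$lower / lam,
      pct_hi = 100 * .data$upper / lam,
      mutator = !is.na(.data$lower) & .data$lower > 0
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$driver, y = .data$pct,
                                   colour = .data$mutator)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$pct_lo,
                                          ymax = .data$pct_hi)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "rate increase (% of baseline)",
                  colour = "mutator") +
    ggplot2::theme_minimal()
}

#' Plot mean alteration times per driver
#'
#' @param times Output of [mean_alteration_times()].
#' @return A ggplot object.
#' @export
plot_alteration_times <- function(times) {
  p <- ggplot2::ggplot(times, ggplot2::aes(
    x = stats::reorder(.data$driver, .data$mean_time), y = .data$mean_time))
  if (all(c("lower", "upper") %in% names(times))) {
    p <- p + ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                                   ymax = .data$upper))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean alteration time (cell divisions)") +
    ggplot2::theme_minimal()
}
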