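#' Plot a latency histogram
#'
#' Bar plot of the relative-frequency latency histogram with the baseline
#' frequency and (optionally) a response window overlaid.
#'
#' @param object a [build_latency_histogram()] result.
#' @param window optional window tibble (with `start`, `end` or
#'   `post_start`, `post_end`) shaded on the plot.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot latency_histogram
#' @export
autoplot.latency_histogram <- function(object, window = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start + attr(object, "bin_width") / 2,
                                        y = .data$freq)) +
    ggplot2::geom_col(width = attr(object, "bin_width"),
                      fill = "steelblue", colour = NA) +
    ggplot2::geom_hline(yintercept = attr(object, "baseline"),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time after trigger (ms)", y = "relative frequency",
                  title = attr(object, "modality")) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    lo <- window$start %||% window$post_start
    hi <- window$end %||% window$post_end
    p <- p + ggplot2::annotate("rect", xmin = lo, xmax = hi,
                               ymin = 0, ymax = Inf, alpha = 0.15,
                               fill = "grey30")
  }
  p
}

#' Plot estimated marginal means by phase
#'
#' EMM +/- SE point-range plot of windowed spike totals before and during DC,
#' the standard visualisation of the reduction analysis.
#'
#' @param emmeans tibble with `level`, `emmean`, `se` (as returned in
#'   [emm_table()]'s `emmeans` element).
#' @return a ggplot object.
#' @export
plot_reduction <- function(emmeans) {
  ggplot2::ggplot(emmeans, ggplot2::aes(x = .data$level, y = .data$emmean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$emmean - .data$se,
                                          ymax = .data$emmean + .data$se)) +
    ggplot2::labs(x = "phase", y = "windowed spike count (EMM ± SE)") +
    ggplot2::theme_minimal()
}

#' Plot post-DC recovery-time distributions
#'
#' @param recovery tibble from [simulate_recovery_study()] or the pipeline's
#'   recovery stage, with `modality`, `recovery_min`, `censored`.
#' @return a ggplot object.
#' @export
plot_recovery <- function(recovery) {
  df <- recovery[!is.na(recovery$recovery_min), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modality, y = .data$recovery_min)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "recovery time (min after DC end)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
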