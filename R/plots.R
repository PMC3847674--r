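# ggplot2 visualisations of fits, studies and threshold sweeps.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_vline geom_boxplot labs position_dodge scale_y_log10 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an EM haplotype-frequency fit
#'
#' Bar chart of the estimated frequencies (variant-position notation on the
#' x axis), optionally overlaying the true frequencies as points.
#'
#' @param object A `hap_em_fit`.
#' @param truth Optional [hap_freq] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hap_em_fit
#' @export
autoplot.hap_em_fit <- function(object, truth = NULL, ...) {
  d <- object$estimates
  d$positions <- factor(d$positions,
                        levels = d$positions[order(-d$estimate)])
  p <- ggplot(d, aes(x = .data$positions, y = .data$estimate)) +
    geom_col(fill = "grey40") +
    labs(x = "variant positions", y = "estimated frequency",
         title = sprintf("%s estimates (%d pools, k = %d)",
                         object$method, object$n_pools, object$k)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (!is.null(truth)) {
    truth <- as_hap_freq(truth)
    td <- tibble(positions = hap_positions(truth$haplotype),
                 freq = truth$freq)
    td <- td[td$positions %in% levels(d$positions), ]
    p <- p + geom_point(data = td, aes(y = .data$freq), colour = "red")
  }
  p
}

#' Plot simulation-study error distributions
#'
#' Boxplots of the per-replicate metric (sum of squared errors by default)
#' by estimator.
#'
#' @param object A `hap_study`.
#' @param metric One of `"sse"`, `"missed"`, `"remaining"`, `"list_length"`,
#'   `"f0_hat"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hap_study
#' @export
autoplot.hap_study <- function(object, metric = "sse", ...) {
  stopifnot(metric %in% c("sse", "missed", "remaining", "list_length",
                          "f0_hat"))
  ggplot(object$metrics,
         aes(x = .data$estimator, y = .data[[metric]])) +
    geom_boxplot() +
    labs(x = NULL, y = metric,
         title = sprintf("n = %d pools, k = %d, %d replicates",
                         object$n, object$k, object$replicates)) +
    theme_minimal()
}

#' Plot a trimming-threshold sweep
#'
#' Mean sum of squared errors of the augmented-and-trimmed EM against the
#' fixed trimming threshold, with the SSE-optimal threshold (dashed) and the
#' average adaptively selected threshold (dotted) marked.
#'
#' @param object A `hap_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hap_sweep
#' @export
autoplot.hap_sweep <- function(object, ...) {
  ggplot(object$by_threshold,
         aes(x = .data$threshold, y = .data$mean_sse)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$optimal, linetype = "dashed") +
    geom_vline(xintercept = object$mean_adaptive, linetype = "dotted") +
    labs(x = "trimming threshold", y = "mean sum of squared errors",
         title = sprintf("n = %d, k = %d, %d replicates",
                         object$n, object$k, object$replicates),
         subtitle = "dashed: SSE-optimal; dotted: mean adaptive selection") +
    theme_minimal()
}
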