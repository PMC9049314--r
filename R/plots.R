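#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a VAF distribution
#'
#' @param object A `vaf_sample`.
#' @param binwidth Histogram bin width (default 0.01).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vaf_sample <- function(object, binwidth = 0.01, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = vaf)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = NA) +
    ggplot2::coord_cartesian(xlim = c(0, max(1, max(object$vaf)))) +
    ggplot2::labs(
      x = "Variant allele frequency",
      y = "Mutations",
      title = sprintf("%s sample: %d mutations, %.0fx mean depth",
                      attr(object, "provenance"), nrow(object),
                      attr(object, "mean_depth"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an approximate posterior from Monte Carlo dropout draws
#'
#' @param object A `posterior_summary`.
#' @param ... Unused.
#' @return A ggplot showing the draw density, mean, and 89% equal-tailed
#'   interval.
#' @export
autoplot.posterior_summary <- function(object, ...) {
  df <- tibble(draw = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = draw)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 1) +
    ggplot2::geom_vline(xintercept = c(object$eti_lower, object$eti_upper),
                        linetype = 2) +
    ggplot2::labs(
      x = "Posterior draw", y = "Density",
      title = sprintf("mean %.3f, %d%% ETI [%.3f, %.3f], T = %d",
                      object$mean, round(100 * object$level),
                      object$eti_lower, object$eti_upper, object$T)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an evolution report: clustered VAF distribution with subclone calls
#'
#' @param object An `evolution_report`.
#' @param binwidth Histogram bin width (default 0.01).
#' @param ... Unused.
#' @return A ggplot of the (purity-corrected, adjusted) VAF distribution,
#'   coloured by cluster assignment, with dashed lines at the estimated
#'   subclone frequencies.
#' @export
autoplot.evolution_report <- function(object, binwidth = 0.01, ...) {
  df <- as_tibble(object$clusters)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = vaf, fill = cluster)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "stack", colour = NA) +
    ggplot2::scale_fill_manual(values = c(
      tail = "grey60", clonal = "#2c7fb8", subclone_1 = "#d95f0e",
      subclone_2 = "#fec44f")) +
    ggplot2::labs(
      x = "Variant allele frequency (purity-corrected)", y = "Mutations",
      title = sprintf("%s, %d subclone(s); P(Selection) = %.2f [%.2f, %.2f]",
                      object$call$mode, object$call$n_subclones,
                      object$call$p_sel$mean, object$call$p_sel$eti_lower,
                      object$call$p_sel$eti_upper)
    ) +
    ggplot2::theme_minimal()
  for (s in object$frequencies) {
    p <- p + ggplot2::geom_vline(xintercept = s$mean, linetype = 2)
  }
  p
}

#' Plot training history
#'
#' @param net A trained `evo_net` or `evo_net_transfer`.
#' @return A ggplot of train/validation loss per epoch.
#' @export
plot_training_history <- function(net) {
  h <- net$meta$history
  stop_unless(!is.null(h), "network has no training history")
  df <- tidyr::pivot_longer(h, -"epoch", names_to = "task",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = value, colour = task)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}
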