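#' Plot a per-residue aggregation profile
#'
#' Line plot of the aggregation score along the sequence with the
#' classification threshold and called APRs (runs of at least `min_length`
#' residues at or above the threshold) shaded.
#'
#' @param object A [residue_profile][profile_sequence].
#' @param threshold Threshold to draw; default: the profile's stored value.
#' @param min_length Minimum APR length for shading; default 6.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_profile <- function(object, threshold = NULL,
                                     min_length = 6L, ...) {
  threshold <- threshold %||% attr(object, "threshold") %||% 0.5
  calls <- call_aprs(object, threshold, min_length)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(color = "#2c3e70") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "grey40") +
    ggplot2::facet_wrap(~sequence_id, ncol = 1, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "residue position", y = "aggregation score") +
    ggplot2::theme_minimal()
  if (nrow(calls) > 0) {
    p <- p + ggplot2::geom_rect(
      data = calls,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
      ymin = -Inf, ymax = Inf, fill = "#c0392b", alpha = 0.15,
      inherit.aes = FALSE)
  }
  p
}

#' @rdname autoplot.residue_profile
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_path(color = "#2c3e70") +
    ggplot2::labs(x = "1 - specificity", y = "recall",
                  subtitle = sprintf("AuROCC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.residue_profile
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path(color = "#2c3e70") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  subtitle = sprintf("AuPRC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.residue_profile
#' @export
autoplot.apr_network <- function(object, ...) {
  h <- tidy(object)
  if (nrow(h) == 0) stop_input("network has no training history to plot")
  long <- tidyr::pivot_longer(h, c("train_auc", "val_auc"),
                              names_to = "series", values_to = "auc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$auc,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$stopping_epoch,
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "epoch", y = "AuROCC", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
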