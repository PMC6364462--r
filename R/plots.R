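#' Plot a ranked variant list
#'
#' Score against rank for one prioritized patient, with the phenotype
#' similarity feature mapped to color — causative candidates typically stand
#' out at the top-left with both high score and high similarity.
#'
#' @param object A `ranked_variants` tibble from [prioritize()].
#' @param highlight Optional tibble of variants (chrom, pos, ref, alt) to
#'   mark, e.g. a known causative.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_variants <- function(object, highlight = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$score,
                                            color = .data$sim)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_color_viridis_c(name = "phenotype\nsimilarity") +
    ggplot2::labs(x = "rank", y = "prediction score") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hit <- object[.variant_key(object) %in% .variant_key(highlight), ]
    p <- p + ggplot2::geom_point(data = hit, shape = 21, size = 3.5,
                                 stroke = 1, color = "red")
  }
  p
}

#' Plot the causative-rank distribution of a spike-in evaluation
#'
#' Histogram of the rank at which the inserted causative variant was
#' recovered across patients, with top-1/top-10 shares in the subtitle.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$ranks, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0.5,
                            fill = "steelblue", color = "white") +
    ggplot2::labs(
      x = "rank of causative variant", y = "patients",
      subtitle = sprintf("top-1 %.1f%%, top-10 %.1f%%, ROC AUC %.3f, AUPR %.3f",
                         100 * object$top1_fraction,
                         100 * object$top10_fraction,
                         object$roc_auc, object$aupr)) +
    ggplot2::theme_minimal()
}

#' Plot training and validation loss curves
#'
#' @param object An `mlp_model` or `pvp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlp_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
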