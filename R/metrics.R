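# Ranking metrics shared by the evaluation machinery.

#' Area under the ROC curve
#'
#' Computed via \pkg{pROC} with fixed direction (higher score = positive
#' class), which handles tied scores by the midrank/trapezoid convention: a
#' constant scorer gets exactly 0.5.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision with tied scores handled as blocks: descending distinct
#' score thresholds, each contributing its recall increment times the
#' precision at that threshold.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  grp <- cumsum(!duplicated(scores))           # tie blocks, best first
  tp_blk <- tapply(labels == 1, grp, sum)
  n_blk <- tapply(labels, grp, length)
  tp <- cumsum(tp_blk)
  n_seen <- cumsum(n_blk)
  precision <- tp / n_seen
  sum((tp_blk / n_pos) * precision)
}
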