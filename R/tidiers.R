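#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-epoch training log of a fitted model
#'
#' @param x An `mlp_model` or `pvp_model`.
#' @param ... Unused.
#' @return A tibble with one row per (epoch, loss type): `epoch`, `set`
#'   (`train`/`validation`), `loss`.
#' @export
tidy.mlp_model <- function(x, ...) {
  out <- tidyr::pivot_longer(x$training_log, c("train_loss", "val_loss"),
                             names_to = "set", values_to = "loss")
  out$set <- ifelse(out$set == "train_loss", "train", "validation")
  out[!is.na(out$loss), ]
}

#' One-row summary of a fitted model
#'
#' @param x An `mlp_model` or `pvp_model`.
#' @param ... Unused.
#' @return Tibble: input width, architecture, parameter count, epochs, final
#'   train and validation loss.
#' @export
glance.mlp_model <- function(x, ...) {
  tibble::tibble(
    input_dim = x$input_dim,
    architecture = paste(c(x$input_dim, x$config$hidden_units, 1L),
                         collapse = "-"),
    n_parameters = sum(vapply(x$weights, function(w)
      length(w$W) + length(w$b), 0)),
    epochs = x$config$epochs,
    train_loss = utils::tail(x$training_log$train_loss, 1L),
    val_loss = utils::tail(x$training_log$val_loss, 1L))
}

#' Tidy per-patient causative-variant ranks
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble: patient, disease, rank, n_variants.
#' @export
tidy.eval_report <- function(x, ...) x$ranks

#' One-row summary of a spike-in evaluation
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble: n, top1, top10, top1_fraction, top10_fraction, roc_auc,
#'   aupr.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, top1 = x$top1, top10 = x$top10,
                 top1_fraction = x$top1_fraction,
                 top10_fraction = x$top10_fraction,
                 roc_auc = x$roc_auc, aupr = x$aupr)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-outer-fold metrics tibble.
#' @export
tidy.cv_result <- function(x, ...) x$metrics

#' One-row summary of a nested cross-validation
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with fold-averaged accuracy, ROC AUC and AUPR.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(folds = nrow(x$metrics),
                 accuracy = mean(x$metrics$accuracy),
                 roc_auc = mean(x$metrics$roc_auc),
                 aupr = mean(x$metrics$aupr))
}
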