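#' Model configuration for the feed-forward classifier
#'
#' Defaults follow the reference architecture: three hidden layers of 67, 32
#' and 256 rectified-linear units, a single logistic output, dropout between
#' the last hidden layer and the output, Adam (learning rate 0.001, standard
#' moment decays), binary cross-entropy loss, batch size 2500, 100 epochs,
#' and a 20% validation split that is disjoint by disease.
#'
#' @param hidden_units Integer vector of hidden layer widths (2-4 layers).
#' @param dropout_rate Dropout probability on the last hidden layer during
#'   training (0 disables).
#' @param learning_rate,batch_size,epochs Adam step size, minibatch size,
#'   number of passes.
#' @param validation_fraction Fraction of disease groups held out for the
#'   per-epoch validation loss.
#' @param seed Integer seed: weight initialization, shuffling, dropout masks
#'   and the validation split all derive from it.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_units = c(67L, 32L, 256L), dropout_rate = 0.5,
                         learning_rate = 0.001, batch_size = 2500L,
                         epochs = 100L, validation_fraction = 0.2,
                         seed = 1L) {
  stopifnot(length(hidden_units) >= 1L, all(hidden_units >= 1L),
            dropout_rate >= 0, dropout_rate < 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "model_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# He initialization for ReLU layers, Glorot for the logistic output.
.init_weights <- function(dims) {
  L <- length(dims) - 1L
  lapply(seq_len(L), function(l) {
    fan_in <- dims[l]
    sd <- if (l < L) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    list(W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sd),
                    fan_in, dims[l + 1L]),
         b = rep(0, dims[l + 1L]))
  })
}

# Forward pass. Returns activations per layer; applies an inverted-dropout
# mask to the last hidden layer when `drop_mask` is supplied.
.forward <- function(x, weights, drop_mask = NULL) {
  L <- length(weights)
  a <- vector("list", L + 1L)
  a[[1L]] <- x
  for (l in seq_len(L)) {
    z <- sweep(a[[l]] %*% weights[[l]]$W, 2, weights[[l]]$b, `+`)
    a[[l + 1L]] <- if (l < L) pmax(z, 0) else .sigmoid(z)
    if (l == L - 1L && !is.null(drop_mask)) {
      a[[l + 1L]] <- a[[l + 1L]] * drop_mask
    }
  }
  a
}

# Backpropagation of mean BCE through sigmoid output and ReLU hidden layers.
.backward <- function(a, y, weights, drop_mask = NULL) {
  L <- length(weights)
  n <- nrow(a[[1L]])
  grads <- vector("list", L)
  delta <- (a[[L + 1L]] - y) / n        # dL/dz at the output (BCE + sigmoid)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(a[[l]], delta), b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(weights[[l]]$W)
      if (l - 1L == L - 1L && !is.null(drop_mask)) delta <- delta * drop_mask
      delta <- delta * (a[[l]] > 0)
    }
  }
  grads
}

#' Train the feed-forward variant classifier
#'
#' Minimizes binary cross-entropy with Adam over minibatches. A
#' `validation_fraction` share of the disease groups (not of the rows) is
#' held out and its loss recorded per epoch, so no disease contributes to
#' both portions of the fit. Dropout (inverted scaling) is applied between
#' the last hidden layer and the output during training only. Training is
#' deterministic for a given seed under single-threaded BLAS.
#'
#' @param x Numeric feature matrix (rows = instances).
#' @param y 0/1 labels.
#' @param groups Disease ID per row, used for the stratified validation
#'   split; rows with `NA` are grouped per variant key when `variant_key` is
#'   supplied, else each forms its own group.
#' @param config A [model_config()].
#' @param variant_key Optional character key per row for grouping unlabeled
#'   (no-disease) rows.
#' @return An `mlp_model`: layer weights, config, and a `training_log`
#'   tibble (epoch, train_loss, val_loss).
#' @export
train_mlp <- function(x, y, groups, config = model_config(),
                      variant_key = NULL) {
  stopifnot(nrow(x) == length(y), length(groups) == length(y))
  if (length(unique(y)) < 2L) stop("training labels are single-class")
  groups <- as.character(groups)
  na_g <- is.na(groups)
  if (any(na_g)) {
    groups[na_g] <- if (!is.null(variant_key)) {
      paste0("VAR:", variant_key[na_g])
    } else paste0("ROW:", which(na_g))
  }

  withr::with_seed(config$seed, {
    ug <- sort(unique(groups))
    n_val <- floor(config$validation_fraction * length(ug))
    val_groups <- if (n_val > 0L) sample(ug, n_val) else character(0)
    is_val <- groups %in% val_groups
    if (all(is_val)) stop("validation split consumed all groups")
    x_tr <- x[!is_val, , drop = FALSE]; y_tr <- y[!is_val]
    x_va <- x[is_val, , drop = FALSE]; y_va <- y[is_val]
    if (length(unique(y_tr)) < 2L) stop("training portion is single-class")

    dims <- c(ncol(x), config$hidden_units, 1L)
    weights <- .init_weights(dims)
    m <- lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0))
    v <- m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    p_keep <- 1 - config$dropout_rate
    log <- matrix(NA_real_, config$epochs, 2L)

    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(nrow(x_tr))
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      for (b in batches) {
        drop_mask <- NULL
        if (config$dropout_rate > 0) {
          drop_mask <- matrix(
            stats::rbinom(length(b) * dims[length(dims) - 1L], 1L, p_keep) / p_keep,
            length(b), dims[length(dims) - 1L])
        }
        a <- .forward(x_tr[b, , drop = FALSE], weights, drop_mask)
        grads <- .backward(a, y_tr[b], weights, drop_mask)
        t_step <- t_step + 1L
        for (l in seq_along(weights)) {
          for (p in c("W", "b")) {
            g <- grads[[l]][[p]]
            m[[l]][[p]] <- beta1 * m[[l]][[p]] + (1 - beta1) * g
            v[[l]][[p]] <- beta2 * v[[l]][[p]] + (1 - beta2) * g^2
            m_hat <- m[[l]][[p]] / (1 - beta1^t_step)
            v_hat <- v[[l]][[p]] / (1 - beta2^t_step)
            weights[[l]][[p]] <- weights[[l]][[p]] -
              config$learning_rate * m_hat / (sqrt(v_hat) + eps)
          }
        }
      }
      log[epoch, 1L] <- .bce(.forward(x_tr, weights)[[length(weights) + 1L]], y_tr)
      log[epoch, 2L] <- if (nrow(x_va) > 0L) {
        .bce(.forward(x_va, weights)[[length(weights) + 1L]], y_va)
      } else NA_real_
    }
  })

  structure(list(
    weights = weights, config = config, input_dim = ncol(x),
    val_groups = val_groups,
    training_log = tibble::tibble(epoch = seq_len(config$epochs),
                                  train_loss = log[, 1L],
                                  val_loss = log[, 2L])
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("<mlp_model> ", x$input_dim, " -> ",
      paste(x$config$hidden_units, collapse = " -> "), " -> 1 (ReLU/sigmoid)",
      "\n  final loss: train ",
      format(utils::tail(x$training_log$train_loss, 1), digits = 4),
      ", validation ",
      format(utils::tail(x$training_log$val_loss, 1), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Predict causative-variant scores
#'
#' Deterministic forward pass (dropout disabled); logistic outputs in (0, 1).
#'
#' @param object An `mlp_model` or `pvp_model`.
#' @param x Feature matrix with `input_dim` columns.
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict.mlp_model <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != object$input_dim) {
    stop("feature width ", ncol(x), " does not match model input width ",
         object$input_dim)
  }
  as.numeric(.forward(x, object$weights)[[length(object$weights) + 1L]])
}

#' Hyperparameter search over the reference space
#'
#' Samples `trials` configurations from the search space — 2 to 4 hidden
#' layers, layer widths from {32, 64, 67, 128, 134, 201, 256, 512}, batch
#' size from {2500, 5000, 10000, 15000, 20000} — trains each for `epochs`
#' epochs, and returns the configuration with the lowest final validation
#' loss. The sampler is pluggable; the default draws uniformly at random
#' from the space.
#'
#' @inheritParams train_mlp
#' @param trials Number of sampled configurations.
#' @param epochs Training epochs per trial (reduced relative to the final
#'   fit).
#' @param seed Seed for sampling and for each trial's training.
#' @param sampler Function `(i)` returning a list with `hidden_units` and
#'   `batch_size`; the default uniform sampler respects the space above.
#' @return The best [model_config()], with the per-trial results in the
#'   `trials` attribute.
#' @export
tune_mlp <- function(x, y, groups, trials = 50L, epochs = 50L, seed = 1L,
                     sampler = NULL, variant_key = NULL) {
  draws <- .sample_search_space(trials, seed, sampler)
  results <- lapply(seq_len(trials), function(i) {
    cfg <- model_config(hidden_units = draws[[i]]$hidden_units,
                        batch_size = draws[[i]]$batch_size,
                        epochs = epochs, seed = seed + i)
    fit <- train_mlp(x, y, groups, cfg, variant_key = variant_key)
    list(config = cfg,
         val_loss = utils::tail(fit$training_log$val_loss, 1L))
  })
  losses <- vapply(results, `[[`, double(1), "val_loss")
  best <- results[[which.min(losses)]]$config
  structure(best, trials = tibble::tibble(
    trial = seq_len(trials),
    layers = vapply(results, function(r) length(r$config$hidden_units), 0L),
    units = vapply(results, function(r)
      paste(r$config$hidden_units, collapse = "x"), ""),
    batch_size = vapply(results, function(r) r$config$batch_size, 0L),
    val_loss = losses))
}

# Reference search space: 2-4 hidden layers, widths from
# {32,64,67,128,134,201,256,512}, batch size from {2500,...,20000}.
.sample_search_space <- function(trials, seed, sampler = NULL) {
  units_space <- c(32L, 64L, 67L, 128L, 134L, 201L, 256L, 512L)
  batch_space <- c(2500L, 5000L, 10000L, 15000L, 20000L)
  if (is.null(sampler)) {
    sampler <- function(i) {
      list(hidden_units = sample(units_space, sample(2:4, 1L), replace = TRUE),
           batch_size = sample(batch_space, 1L))
    }
  }
  withr::with_seed(seed, lapply(seq_len(trials), sampler))
}

# ---- full prioritization model (network + schema + imputation) ------------

#' Fit the full prioritization model on a training set
#'
#' Encodes the training set, fits mean imputation on it, and trains the
#' network; the returned model bundles the weights with the feature schema
#' and imputation means so it can score new patients end to end.
#'
#' @param ts A `training_set` from [build_training_set()].
#' @param kb,store,onto,ic Knowledge resources used for encoding.
#' @param config A [model_config()].
#' @return A `pvp_model`: the `mlp_model` fields plus `schema` and
#'   `imputation`.
#' @export
fit_pvp <- function(ts, kb, store, onto, ic, config = model_config()) {
  schema <- feature_schema(onto)
  enc <- encode_training(ts, kb, store, onto, ic, schema)
  fit <- train_mlp(enc$x, enc$y, enc$groups, config,
                   variant_key = .variant_key(ts))
  fit$schema <- schema
  fit$imputation <- enc$imputation
  class(fit) <- c("pvp_model", class(fit))
  fit
}

#' Persist / restore a fitted model
#'
#' The model directory holds plain-text artifacts: one TSV per layer's
#' weights and biases, the feature schema and configuration as JSON (with
#' the imputation means), and the training log as TSV.
#'
#' @param model A `pvp_model`.
#' @param dir Directory (created if needed).
#' @return `dir` invisibly; [read_pvp()] returns the restored `pvp_model`.
#' @export
write_pvp <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_along(model$weights)) {
    utils::write.table(model$weights[[l]]$W,
                       file.path(dir, sprintf("W%d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(t(model$weights[[l]]$b),
                       file.path(dir, sprintf("b%d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(config = unclass(model$config),
                            input_dim = model$input_dim,
                            n_layers = length(model$weights),
                            imputation = as.list(model$imputation$means)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_schema(model$schema, file.path(dir, "schema.json"))
  readr::write_tsv(model$training_log, file.path(dir, "training_log.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_pvp
#' @export
read_pvp <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  weights <- lapply(seq_len(meta$n_layers), function(l) {
    W <- as.matrix(utils::read.table(file.path(dir, sprintf("W%d.tsv", l)),
                                     sep = "\t"))
    dimnames(W) <- NULL
    b <- as.numeric(utils::read.table(file.path(dir, sprintf("b%d.tsv", l)),
                                      sep = "\t"))
    list(W = W, b = b)
  })
  cfg <- meta$config
  structure(list(
    weights = weights,
    config = model_config(hidden_units = cfg$hidden_units,
                          dropout_rate = cfg$dropout_rate,
                          learning_rate = cfg$learning_rate,
                          batch_size = cfg$batch_size, epochs = cfg$epochs,
                          validation_fraction = cfg$validation_fraction,
                          seed = cfg$seed),
    input_dim = as.integer(meta$input_dim),
    training_log = readr::read_tsv(file.path(dir, "training_log.tsv"),
                                   col_types = "idd", progress = FALSE),
    schema = read_schema(file.path(dir, "schema.json")),
    imputation = structure(list(means = unlist(meta$imputation)),
                           class = "imputation_model")
  ), class = c("pvp_model", "mlp_model"))
}
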