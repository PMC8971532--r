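# The MFNN inverse surrogate: input standardization, max-abs target
# normalization, training with minibatch Adam on an MAE loss with
# best-validation-checkpoint early stopping, prediction, error metrics and
# the network-structure cross-validation scan.

#' Surrogate hyperparameter configuration
#'
#' Defaults follow the tuned final structure: two hidden layers of 1024
#' rectifier units, Adam at learning rate 1e-4, batch size 32, 10,000
#' epochs for final training (2,000 during cross-validation), ten-fold CV,
#' and a 10% validation holdout used for best-checkpoint selection.
#'
#' @param hidden_layers Number of hidden layers (1-3).
#' @param units Units per hidden layer (64-1024).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param cv_folds Cross-validation folds.
#' @param val_fraction Validation holdout fraction of the training pool.
#' @param seed Integer seed for weight initialization and shuffling.
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(hidden_layers = 2, units = 1024,
                             learning_rate = 1e-4, batch_size = 32,
                             epochs = 10000, cv_folds = 10,
                             val_fraction = 0.1, seed = 1) {
  stopifnot(hidden_layers >= 1, hidden_layers <= 3,
            units >= 2, units <= 1024, epochs >= 1)
  structure(list(hidden_layers = hidden_layers, units = units,
                 learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, cv_folds = cv_folds,
                 val_fraction = val_fraction, seed = seed),
            class = "surrogate_config")
}

#' Fit input/output scalers on training data
#'
#' Inputs are standardized per column (subtract mean, divide by standard
#' deviation); targets are normalized per column by their maximum absolute
#' value. Zero-variance input columns are flagged and their scale clamped
#' to 1 with a warning.
#'
#' @param X Training input matrix.
#' @param Y Training target matrix.
#' @return A list of class `surrogate_scalers` with `x_mean`, `x_sd`,
#'   `y_maxabs`, `constant_cols`.
#' @export
fit_scalers <- function(X, Y) {
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  const <- which(x_sd == 0 | !is.finite(x_sd))
  if (length(const)) {
    warning(sprintf("%d zero-variance input column(s) clamped to unit scale",
                    length(const)))
    x_sd[const] <- 1
  }
  y_maxabs <- apply(abs(Y), 2, max)
  if (any(y_maxabs == 0)) stop("degenerate target column")
  structure(list(x_mean = x_mean, x_sd = x_sd, y_maxabs = y_maxabs,
                 constant_cols = const),
            class = "surrogate_scalers")
}

scale_inputs <- function(scalers, X)
  sweep(sweep(X, 2, scalers$x_mean), 2, scalers$x_sd, "/")

normalize_targets <- function(scalers, Y) sweep(Y, 2, scalers$y_maxabs, "/")

rescale_targets <- function(scalers, Yn) sweep(Yn, 2, scalers$y_maxabs, "*")

#' Train the MFNN surrogate
#'
#' Splits off a validation fraction of the training pool (seeded), fits the
#' scalers on the remaining training examples only, and trains the network
#' with minibatch Adam on the MAE loss over normalized targets. The
#' checkpoint with the lowest validation loss is returned (best-checkpoint
#' early stopping).
#'
#' @param ds A `stiff_dataset` with a train split (see [split_dataset()]),
#'   or a plain input matrix when `Y` is given.
#' @param cfg A [surrogate_config()].
#' @param Y Target matrix when `ds` is a matrix.
#' @return An object of class `stiff_surrogate` with the network weights,
#'   scalers, per-epoch training history and configuration.
#' @export
train_surrogate <- function(ds, cfg = surrogate_config(), Y = NULL) {
  if (inherits(ds, "stiff_dataset")) {
    idx <- if (length(ds$split)) ds$split$train else seq_len(nrow(ds$inputs))
    X <- ds$inputs[idx, , drop = FALSE]
    Y <- ds$targets[idx, , drop = FALSE]
  } else X <- ds
  n <- nrow(X)
  n_val <- max(1L, round(cfg$val_fraction * n))
  val <- with_seed(cfg$seed, sort(sample.int(n, n_val)))
  tr <- setdiff(seq_len(n), val)
  scalers <- fit_scalers(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
  Xtr <- scale_inputs(scalers, X[tr, , drop = FALSE])
  Ytr <- normalize_targets(scalers, Y[tr, , drop = FALSE])
  Xv <- scale_inputs(scalers, X[val, , drop = FALSE])
  Yv <- normalize_targets(scalers, Y[val, , drop = FALSE])
  fit <- .mlp_train_cpp(Xtr, Ytr, Xv, Yv,
                        rep(cfg$units, cfg$hidden_layers),
                        cfg$learning_rate, cfg$batch_size, cfg$epochs,
                        cfg$seed)
  structure(list(weights = fit$weights, biases = fit$biases,
                 scalers = scalers,
                 history = data.frame(epoch = seq_len(cfg$epochs),
                                      train_loss = fit$train_loss,
                                      val_loss = fit$val_loss),
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 feature_names = colnames(X), config = cfg),
            class = "stiff_surrogate")
}

#' @export
print.stiff_surrogate <- function(x, ...) {
  cat(sprintf(
    "MFNN surrogate: %d -> %s -> %d; best val MAE %.5g at epoch %d/%d\n",
    length(x$scalers$x_mean),
    paste(rep(x$config$units, x$config$hidden_layers), collapse = " -> "),
    length(x$scalers$y_maxabs), x$best_val_loss, x$best_epoch,
    x$config$epochs))
  invisible(x)
}

# forward pass through the stored network (inputs already standardized)
forward_mfnn <- function(model, Xs) {
  A <- Xs
  L <- length(model$weights)
  for (l in seq_len(L)) {
    A <- A %*% model$weights[[l]]
    A <- sweep(A, 2, as.numeric(model$biases[[l]]), "+")
    if (l < L) A[A < 0] <- 0
  }
  A
}

#' Predict fiber constants from input features
#'
#' @param object A trained `stiff_surrogate`.
#' @param newdata A 114-element vector or a matrix with one input per row
#'   (feature count must match the trained model).
#' @param floor Positivity floor; predictions below it are clipped with a
#'   warning (default 0.01, the sampling floor).
#' @param ... Unused.
#' @return Matrix with columns `a_f`, `b_f` in physical units.
#' @export
predict.stiff_surrogate <- function(object, newdata, floor = 0.01, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$scalers$x_mean))
    stop(sprintf("expected %d input features, got %d",
                 length(object$scalers$x_mean), ncol(newdata)))
  Yn <- forward_mfnn(object, scale_inputs(object$scalers, newdata))
  Y <- rescale_targets(object$scalers, Yn)
  if (any(Y < floor)) {
    warning("prediction(s) below the sampling floor were clipped")
    Y[Y < floor] <- floor
  }
  colnames(Y) <- names(object$scalers$y_maxabs)
  Y
}

#' Prediction error metrics
#'
#' Per-target mean absolute error (physical units), normalized mean
#' absolute error (percent of the observed target range) and coefficient
#' of determination (percent):
#' NMAE_i = sum|y - yhat| / (n (max y - min y)),
#' R2_i = 1 - sum (y - yhat)^2 / sum (y - mean y)^2.
#'
#' @param actual,predicted Matrices (or vectors) of matching shape.
#' @return A data.frame with one row per target: `mae`, `nmae_pct`,
#'   `r2_pct`.
#' @export
surrogate_metrics <- function(actual, predicted) {
  actual <- as.matrix(actual); predicted <- as.matrix(predicted)
  stopifnot(all(dim(actual) == dim(predicted)), nrow(actual) >= 2)
  out <- data.frame(target = colnames(actual) %||% paste0("y", seq_len(ncol(actual))),
                    mae = NA_real_, nmae_pct = NA_real_, r2_pct = NA_real_)
  for (i in seq_len(ncol(actual))) {
    y <- actual[, i]; yh <- predicted[, i]
    rng <- max(y) - min(y)
    if (rng == 0) stop("NMAE undefined: target has zero range")
    out$mae[i] <- mean(abs(y - yh))
    out$nmae_pct[i] <- 100 * sum(abs(y - yh)) / (length(y) * rng)
    out$r2_pct[i] <- 100 * (1 - sum((y - yh)^2) / sum((y - mean(y))^2))
  }
  out
}

#' Cross-validation scan over network structures
#'
#' For each candidate structure, runs k-fold cross-validation on the
#' training pool (90/10 splits for ten folds) at the reduced epoch budget
#' and reports fold-averaged per-target MAE, NMAE and R^2.
#'
#' @param ds A `stiff_dataset` (train split used if present).
#' @param structures List of `c(layers, units)` pairs.
#' @param cfg Base [surrogate_config()]; `epochs` here is the CV budget.
#' @param folds Number of folds (default `cfg$cv_folds`).
#' @return A data.frame with one row per structure.
#' @export
cross_validate <- function(ds, structures, cfg = surrogate_config(epochs = 2000),
                           folds = cfg$cv_folds) {
  idx <- if (length(ds$split)) ds$split$train else seq_len(nrow(ds$inputs))
  X <- ds$inputs[idx, , drop = FALSE]
  Y <- ds$targets[idx, , drop = FALSE]
  n <- nrow(X)
  fold_id <- with_seed(cfg$seed, sample(rep_len(seq_len(folds), n)))
  rows <- list()
  for (s in structures) {
    layers <- s[1]; units <- s[2]
    acc <- matrix(0, 2, 3, dimnames = list(c("a_f", "b_f"),
                                           c("mae", "nmae_pct", "r2_pct")))
    for (f in seq_len(folds)) {
      hold <- which(fold_id == f)
      scfg <- surrogate_config(layers, units, cfg$learning_rate,
                               cfg$batch_size, cfg$epochs, cfg$cv_folds,
                               cfg$val_fraction, cfg$seed + f)
      # fold holdout doubles as the validation set for checkpointing
      scalers <- fit_scalers(X[-hold, , drop = FALSE], Y[-hold, , drop = FALSE])
      fit <- .mlp_train_cpp(scale_inputs(scalers, X[-hold, , drop = FALSE]),
                            normalize_targets(scalers, Y[-hold, , drop = FALSE]),
                            scale_inputs(scalers, X[hold, , drop = FALSE]),
                            normalize_targets(scalers, Y[hold, , drop = FALSE]),
                            rep(units, layers), cfg$learning_rate,
                            cfg$batch_size, cfg$epochs, cfg$seed + f)
      model <- structure(list(weights = fit$weights, biases = fit$biases,
                              scalers = scalers,
                              config = scfg),
                         class = "stiff_surrogate")
      pred <- predict(model, X[hold, , drop = FALSE])
      m <- surrogate_metrics(Y[hold, , drop = FALSE], pred)
      acc <- acc + as.matrix(m[, c("mae", "nmae_pct", "r2_pct")])
    }
    acc <- acc / folds
    rows[[length(rows) + 1]] <- data.frame(
      structure = sprintf("%dx%d", layers, units),
      mae_af = acc["a_f", "mae"], mae_bf = acc["b_f", "mae"],
      nmae_af = acc["a_f", "nmae_pct"], nmae_bf = acc["b_f", "nmae_pct"],
      r2_af = acc["a_f", "r2_pct"], r2_bf = acc["b_f", "r2_pct"])
  }
  do.call(rbind, rows)
}

#' Save / load a trained surrogate as a portable text directory
#'
#' Weights, scalers, history and configuration are written as delimited
#' text and a JSON manifest.
#'
#' @param model A `stiff_surrogate`.
#' @param dir Directory path (created if needed).
#' @export
save_surrogate <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = unclass(model$config),
    feature_names = model$feature_names,
    best_epoch = model$best_epoch, best_val_loss = model$best_val_loss,
    scalers = list(x_mean = as.list(model$scalers$x_mean),
                   x_sd = as.list(model$scalers$x_sd),
                   y_maxabs = as.list(model$scalers$y_maxabs),
                   constant_cols = model$scalers$constant_cols),
    n_layers = length(model$weights))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (l in seq_along(model$weights)) {
    utils::write.table(format(model$weights[[l]], digits = 17),
                       file.path(dir, sprintf("W%d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    writeLines(sprintf("%.17g", as.numeric(model$biases[[l]])),
               file.path(dir, sprintf("b%d.txt", l)))
  }
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  L <- man$n_layers
  weights <- lapply(seq_len(L), function(l)
    as.matrix(utils::read.table(file.path(dir, sprintf("W%d.tsv", l)),
                                sep = "\t")))
  biases <- lapply(seq_len(L), function(l)
    as.numeric(readLines(file.path(dir, sprintf("b%d.txt", l)))))
  scalers <- structure(list(
    x_mean = unlist(man$scalers$x_mean), x_sd = unlist(man$scalers$x_sd),
    y_maxabs = unlist(man$scalers$y_maxabs),
    constant_cols = man$scalers$constant_cols %||% integer(0)),
    class = "surrogate_scalers")
  hist_file <- file.path(dir, "history.csv")
  structure(list(weights = lapply(weights, unname), biases = biases,
                 scalers = scalers,
                 history = if (file.exists(hist_file))
                   utils::read.csv(hist_file) else NULL,
                 best_epoch = man$best_epoch,
                 best_val_loss = man$best_val_loss,
                 feature_names = man$feature_names,
                 config = do.call(surrogate_config, man$config)),
            class = "stiff_surrogate")
}
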