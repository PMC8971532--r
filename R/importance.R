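# Permutation feature importance over the trained surrogate, and the
# feature-reduction retraining workflow.

#' Permutation feature importance
#'
#' Computes the reference MAE score s of the model on the supplied data
#' (normalized-target MAE, the training loss), then for each feature j and
#' repetition k shuffles column j (seeded) and recomputes the corrupted
#' score s_kj. Importance is reported as the mean score degradation
#' i_j = mean_k(s_kj) - s, so features the model relies on come out
#' positive.
#'
#' @param model A trained `stiff_surrogate`.
#' @param X Input matrix (training/validation data by default usage).
#' @param Y Matching target matrix.
#' @param K Number of shuffling repetitions (default 10).
#' @param seed Integer seed for the permutations.
#' @return An object of class `importance_result`: data.frame `importance`
#'   (feature, i_j), reference score `s`, matrix `scores` (K x features).
#' @export
permutation_importance <- function(model, X, Y, K = 10, seed = 1) {
  if (is.null(model$weights)) stop("model is not trained")
  stopifnot(K >= 1, nrow(X) == nrow(Y))
  score <- function(Xd) {
    Yn <- forward_mfnn(model, scale_inputs(model$scalers, Xd))
    sum(abs(Yn - normalize_targets(model$scalers, Y))) / nrow(Y)
  }
  s <- score(X)
  nf <- ncol(X)
  scores <- matrix(NA_real_, K, nf,
                   dimnames = list(NULL, colnames(X)))
  with_seed(seed, {
    for (k in seq_len(K)) {
      for (j in seq_len(nf)) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        scores[k, j] <- score(Xp)
      }
    }
  })
  structure(list(importance = data.frame(feature = colnames(X),
                                         i_j = colMeans(scores) - s,
                                         row.names = NULL),
                 s = s, K = K, scores = scores),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  top <- x$importance[order(-x$importance$i_j), ][1:min(10, nrow(x$importance)), ]
  cat(sprintf("permutation importance (K = %d, reference MAE %.5g); top features:\n",
              x$K, x$s))
  print(top, row.names = FALSE)
  invisible(x)
}

#' Retrain the surrogate on a reduced feature set
#'
#' Drops the excluded geometric features and retrains with identical
#' hyperparameters; the EDPVR block must always be kept. Test metrics are
#' computed on the dataset's test split for comparison with the
#' full-feature model.
#'
#' @param ds A `stiff_dataset` with train/test split.
#' @param keep Character vector of feature names to keep. The 100 EDPVR
#'   columns are appended automatically if not listed.
#' @param cfg A [surrogate_config()].
#' @return A list with `model`, `metrics` (test-split metrics), `kept`.
#' @export
reduce_and_retrain <- function(ds, keep, cfg = surrogate_config()) {
  if (length(keep) == 0) stop("empty feature set")
  all_feats <- colnames(ds$inputs)
  if (!all(keep %in% all_feats))
    stop("unknown feature(s): ", paste(setdiff(keep, all_feats), collapse = ", "))
  edpvr_cols <- grep("^V[0-9]{3}$", all_feats, value = TRUE)
  kept <- union(keep, edpvr_cols)
  if (!any(edpvr_cols %in% kept)) stop("the EDPVR block must be kept")
  kept <- all_feats[all_feats %in% kept]   # canonical order
  rds <- ds
  rds$inputs <- ds$inputs[, kept, drop = FALSE]
  model <- train_surrogate(rds, cfg)
  test <- rds$split$test
  metr <- NULL
  if (length(test)) {
    pred <- predict(model, rds$inputs[test, , drop = FALSE])
    metr <- surrogate_metrics(rds$targets[test, , drop = FALSE], pred)
  }
  list(model = model, metrics = metr, kept = kept)
}
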