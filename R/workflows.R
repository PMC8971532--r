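# End-to-end workflows: the full training study, the worst-case
# fiber-stress consistency check, and the single-point (Klotz) prediction
# pathway.

#' Default study configuration
#'
#' The full-scale study mirrors the training protocol (25 parents, 2,500
#' LHS examples, 100 held out for testing, 2x1024 network, 10,000 epochs);
#' scaled-down studies are obtained by overriding `n_examples`, `units`
#' and `epochs`.
#'
#' @param n_examples Corpus size.
#' @param n_parents Parent-library size.
#' @param n_test Held-out test examples.
#' @param seed Master seed (parents, LHS, split and network seeds derive
#'   from it).
#' @param cfg A [surrogate_config()].
#' @param reduced_keep Geometric features kept in the reduced model.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_examples = 2500, n_parents = 25, n_test = 100,
                         seed = 1, cfg = surrogate_config(),
                         reduced_keep = c("LV_V", "LV_A",
                                          "theta_endo", "theta_epi")) {
  structure(list(n_examples = n_examples, n_parents = n_parents,
                 n_test = n_test, seed = seed, cfg = cfg,
                 reduced_keep = reduced_keep),
            class = "study_config")
}

#' Run the full training study
#'
#' Parent library -> LHS design -> forward-simulated corpus -> train/test
#' split -> full-feature surrogate -> reduced-feature surrogate; reports
#' held-out metrics for both models and the worst/best test cases.
#'
#' @param config A [study_config()].
#' @param run_reduced Also train the reduced-feature model (default TRUE).
#' @return A `study_report` list: `dataset`, `model`, `metrics_full`,
#'   `reduced` (model + metrics), `cases` (per-test-case errors, ranked),
#'   `provenance`.
#' @export
run_training_study <- function(config = study_config(), run_reduced = TRUE) {
  parents <- make_parent_library(config$n_parents, seed = config$seed)
  samples <- lhs_sample(config$n_examples, seed = config$seed + 1,
                        n_parents = config$n_parents)
  ds <- build_dataset(parents, samples)
  ds <- split_dataset(ds, n_test = config$n_test, seed = config$seed + 2)
  model <- train_surrogate(ds, config$cfg)
  test <- ds$split$test
  pred <- predict(model, ds$inputs[test, , drop = FALSE])
  actual <- ds$targets[test, , drop = FALSE]
  metrics_full <- surrogate_metrics(actual, pred)
  # per-case MAE on normalized targets (the ranking score)
  err_n <- abs(normalize_targets(model$scalers, pred) -
                 normalize_targets(model$scalers, actual))
  cases <- data.frame(test_index = test,
                      a_f_actual = actual[, 1], b_f_actual = actual[, 2],
                      a_f_pred = pred[, 1], b_f_pred = pred[, 2],
                      mae_norm = rowSums(err_n))
  cases <- cases[order(-cases$mae_norm), ]
  reduced <- NULL
  if (run_reduced)
    reduced <- reduce_and_retrain(ds, config$reduced_keep, config$cfg)
  structure(list(dataset = ds, model = model, parents = parents,
                 metrics_full = metrics_full, reduced = reduced,
                 cases = cases,
                 provenance = list(seed = config$seed,
                                   n_examples = config$n_examples,
                                   n_parents = config$n_parents,
                                   n_test = config$n_test,
                                   config = unclass(config$cfg))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study: %d examples (%d test), %dx%d MFNN, %d epochs\n",
              x$provenance$n_examples, x$provenance$n_test,
              x$provenance$config$hidden_layers, x$provenance$config$units,
              x$provenance$config$epochs))
  cat("full-feature test metrics:\n"); print(x$metrics_full)
  if (!is.null(x$reduced)) {
    cat("reduced-feature test metrics:\n"); print(x$reduced$metrics)
  }
  invisible(x)
}

# rebuild the forward-model geometry of a dataset row
.case_geometry <- function(report, row_index) {
  s <- report$dataset$samples[row_index, ]
  geom <- resize(report$parents[[s$parent_id]], s$f_LV, s$f_RV)
  list(cyl = equivalent_cylinder(geom),
       fibers = fiber_layers(s$theta_endo, s$theta_epi))
}

#' Worst-case fiber-stress consistency check
#'
#' Ranks the test cases by prediction MAE; for the `n_worst` worst cases,
#' runs the forward inflation with the actual and with the predicted
#' (a_f, b_f) on the same geometry and fiber architecture and computes the
#' coefficient of determination between the two transmural-maximum fiber
#' stress curves across the load steps.
#'
#' @param report A `study_report` from [run_training_study()].
#' @param n_worst Number of worst-ranked cases to check.
#' @return A data.frame with one row per case: `test_index`, `mae_norm`,
#'   `r2_stress_pct`.
#' @export
worst_case_stress_check <- function(report, n_worst = 1) {
  cases <- report$cases[seq_len(min(n_worst, nrow(report$cases))), ]
  out <- cases[, c("test_index", "mae_norm")]
  out$r2_stress_pct <- NA_real_
  for (i in seq_len(nrow(cases))) {
    gm <- .case_geometry(report, cases$test_index[i])
    act <- fiber_stress_curve(gm$cyl, gm$fibers,
                              material_params(cases$a_f_actual[i],
                                              cases$b_f_actual[i]),
                              report$dataset$grid)
    prd <- fiber_stress_curve(gm$cyl, gm$fibers,
                              material_params(cases$a_f_pred[i],
                                              cases$b_f_pred[i]),
                              report$dataset$grid)
    y <- act$sigma_ff_max; yh <- prd$sigma_ff_max
    out$r2_stress_pct[i] <- 100 * (1 - sum((y - yh)^2) / sum((y - mean(y))^2))
  }
  out
}

#' Predict fiber constants from a single (P_ED, V_ED) point
#'
#' Reconstructs the full EDPVR from the measured point via the universal
#' curve, assembles the 114-element input vector with the supplied
#' geometric and fiber features, and runs the surrogate.
#'
#' @param model A trained `stiff_surrogate` (full 114-feature model).
#' @param geom_features Named vector of the 12 geometric features.
#' @param theta_endo,theta_epi Fiber helix angles (radians).
#' @param P_ED,V_ED The measured end-diastolic point (mmHg, ul).
#' @param uc A `universal_curve` from [fit_universal()].
#' @param grid Pressure grid (must match the training grid).
#' @return A list with `prediction` (a_f, b_f) and the reconstructed
#'   `curve`.
#' @export
predict_from_single_point <- function(model, geom_features, theta_endo,
                                      theta_epi, P_ED, V_ED, uc,
                                      grid = pressure_grid()) {
  if (missing(uc) || is.null(uc)) stop("a fitted universal curve is required")
  curve <- edpvr_from_point(P_ED, V_ED, uc, grid)
  x <- c(geom_features[c("LV_V", "LV_A", "RV_V", "RV_A",
                         paste0("S_A", 1:6), "Epi_V", "Epi_A")],
         theta_endo = theta_endo, theta_epi = theta_epi, curve$volumes)
  list(prediction = predict(model, as.numeric(x)), curve = curve)
}
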