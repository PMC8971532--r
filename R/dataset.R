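# Latin hypercube sampling of the 6-dimensional design space
# (f_LV, f_RV, theta_endo, theta_epi, a_f, b_f), assembly of the training
# corpus (12 geometric + 2 fiber + 100 EDPVR input features, fiber-constant
# targets), splits and tabular I/O.

#' Default sampling ranges of the design space
#'
#' Resize factors in (0.7, 1.6); helix angles in (0, pi/2) at the
#' endocardium and (-pi/2, 0) at the epicardium; fiber constants
#' a_f in (0.01, 100) kPa and b_f in (0.01, 20).
#' @return Named list of `c(min, max)` ranges.
#' @export
design_ranges <- function() {
  list(f_LV = c(0.7, 1.6), f_RV = c(0.7, 1.6),
       theta_endo = c(0, pi / 2), theta_epi = c(-pi / 2, 0),
       a_f = c(0.01, 100), b_f = c(0.01, 20))
}

#' Latin hypercube sample of the design space
#'
#' Each dimension is partitioned into `n` equal-probability intervals and
#' exactly one point falls in every interval of every dimension (uniform
#' jitter within intervals; plain LHS, no maximin optimization). Parents
#' are assigned round-robin over the library so each parent anchors an
#' equal share of the corpus.
#'
#' @param n Number of samples.
#' @param ranges Named list of ranges; see [design_ranges()].
#' @param seed Integer seed.
#' @param n_parents Size of the parent library for round-robin assignment.
#' @return A data.frame with the six design columns plus `parent_id`.
#' @export
lhs_sample <- function(n, ranges = design_ranges(), seed = 1, n_parents = 25) {
  stopifnot(n >= 1)
  for (nm in names(ranges))
    if (ranges[[nm]][1] >= ranges[[nm]][2])
      stop(sprintf("invalid range for %s", nm))
  u <- with_seed(seed, lhs::randomLHS(n, length(ranges)))
  out <- as.data.frame(mapply(function(col, r) r[1] + col * (r[2] - r[1]),
                              as.data.frame(u), ranges, SIMPLIFY = FALSE))
  names(out) <- names(ranges)
  out$parent_id <- ((seq_len(n) - 1) %% n_parents) + 1
  out
}

#' Canonical input feature names
#'
#' 12 geometric features, 2 fiber angles, then the 100 EDPVR volumes
#' (`V001`..`V100` on the standard pressure grid), 114 in total.
#' @return Character vector of length 114.
#' @export
feature_names <- function() {
  c("LV_V", "LV_A", "RV_V", "RV_A",
    paste0("S_A", 1:6), "Epi_V", "Epi_A",
    "theta_endo", "theta_epi",
    sprintf("V%03d", 1:100))
}

#' Build the training corpus from design samples
#'
#' For each design sample: resize the assigned parent, extract the 12
#' geometric features, build the 4-layer fiber architecture, reduce to the
#' equivalent cylinder, inflate over the pressure grid, and pair the
#' 114-element input vector with the (a_f, b_f) targets. Solver failures
#' are logged and excluded; more than 1% failures aborts the build.
#'
#' @param parents Parent library from [make_parent_library()].
#' @param samples Design samples from [lhs_sample()].
#' @param grid Pressure grid in mmHg (default [pressure_grid()]).
#' @param n_gauss Quadrature points per fiber layer.
#' @return An object of class `stiff_dataset`: list with `inputs`
#'   (n x 114 matrix), `targets` (n x 2 matrix), `samples` (provenance),
#'   `grid`, `failures`, and an empty `split`.
#' @export
build_dataset <- function(parents, samples, grid = pressure_grid(),
                          n_gauss = 8) {
  n <- nrow(samples)
  inputs <- matrix(NA_real_, n, 114, dimnames = list(NULL, feature_names()))
  targets <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("a_f", "b_f")))
  failures <- character(0)
  for (i in seq_len(n)) {
    row <- samples[i, ]
    res <- tryCatch({
      geom <- resize(parents[[row$parent_id]], row$f_LV, row$f_RV)
      feats <- geometric_features(geom)
      fibers <- fiber_layers(row$theta_endo, row$theta_epi)
      cyl <- equivalent_cylinder(feats, L = geom$parent$Z_epi)
      pr <- material_params(row$a_f, row$b_f)
      curve <- inflate(cyl, fibers, pr, grid, n_gauss)
      list(feats = feats, vols = curve$volumes)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("example %d: %s", i, conditionMessage(res)))
      next
    }
    inputs[i, ] <- c(res$feats, row$theta_endo, row$theta_epi, res$vols)
    targets[i, ] <- c(row$a_f, row$b_f)
  }
  if (length(failures) > n / 100)
    stop(sprintf("solver failed for %d of %d examples:\n%s",
                 length(failures), n, paste(failures, collapse = "\n")))
  ok <- !is.na(targets[, 1])
  structure(list(inputs = inputs[ok, , drop = FALSE],
                 targets = targets[ok, , drop = FALSE],
                 samples = samples[ok, , drop = FALSE],
                 grid = grid, failures = failures,
                 split = list()),
            class = "stiff_dataset")
}

#' Split a dataset into training/validation and test sets
#'
#' Seeded uniform draw of `n_test` held-out examples; the remainder is the
#' training/validation pool.
#'
#' @param ds A `stiff_dataset`.
#' @param n_test Number of test examples (default 100).
#' @param seed Integer seed.
#' @return The dataset with `split$train` and `split$test` index vectors.
#' @export
split_dataset <- function(ds, n_test = 100, seed = 1) {
  n <- nrow(ds$inputs)
  if (n_test >= n) stop("n_test must be smaller than the dataset size")
  if (n_test == 0) {
    warning("empty test set")
    ds$split <- list(train = seq_len(n), test = integer(0), seed = seed)
    return(ds)
  }
  test <- sort(with_seed(seed, sample.int(n, n_test)))
  ds$split <- list(train = setdiff(seq_len(n), test), test = test, seed = seed)
  ds
}

#' @export
print.stiff_dataset <- function(x, ...) {
  cat(sprintf("stiff_dataset: %d examples x %d input features", nrow(x$inputs),
              ncol(x$inputs)))
  if (length(x$split))
    cat(sprintf(" (train %d / test %d)", length(x$split$train),
                length(x$split$test)))
  cat("\n")
  invisible(x)
}

#' Write / read a dataset as delimited text with a metadata sidecar
#'
#' The table holds the provenance columns, the 114 canonical input columns
#' and the two target columns; seeds, split indices and the pressure grid
#' go to a JSON sidecar `<file>.meta.json`. Values are printed with 17
#' significant digits so a write-read-write round trip is byte-identical.
#'
#' @param ds A `stiff_dataset`.
#' @param file Path of the CSV table.
#' @export
write_dataset <- function(ds, file) {
  d <- cbind(ds$samples[, c("parent_id", "f_LV", "f_RV"), drop = FALSE],
             as.data.frame(ds$inputs), a_f = ds$targets[, 1],
             b_f = ds$targets[, 2])
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) sprintf("%.17g", x))
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  meta <- list(grid = ds$grid, split = ds$split, failures = ds$failures)
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  d <- utils::read.csv(file)
  meta <- jsonlite::read_json(paste0(file, ".meta.json"), simplifyVector = TRUE)
  split <- meta$split
  if (length(split)) split <- lapply(split, function(x) if (is.numeric(x)) as.integer(x) else x)
  inputs <- as.matrix(d[, feature_names()])
  samples <- d[, c("parent_id", "f_LV", "f_RV", "theta_endo", "theta_epi",
                   "a_f", "b_f")]
  structure(list(inputs = inputs,
                 targets = as.matrix(d[, c("a_f", "b_f")]),
                 samples = samples,
                 grid = meta$grid, failures = meta$failures %||% character(0),
                 split = split),
            class = "stiff_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
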