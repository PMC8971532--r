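# Semi-analytic passive inflation of a fiber-reinforced incompressible
# thick-walled cylinder (the reduced-order stand-in for FE pressurization
# of the LV). The base is fixed axially (lambda_z = 1), so incompressible
# plane-strain kinematics give r(R)^2 = r_i^2 + R^2 - R_i^2, and the LV
# pressure balances the transmural integral of the hoop-radial stress
# difference:
#
#   P(r_i) = int_{R_i}^{R_o} [sigma_tt - sigma_rr] / r * (R / r) dR
#
# with sigma_tt - sigma_rr = a e^{b(I1-3)} (lt^2 - lr^2)
#                          + 2 a_f (I4f - 1) e^{b_f (I4f-1)^2} lt^2 cos^2(alpha),
# lt = r/R, lr = R/r, I4f = lt^2 cos^2(alpha) + sin^2(alpha), and alpha
# piecewise constant over the fiber layers. The integral is evaluated by
# per-layer Gauss-Legendre quadrature and r_i found by bracketed root
# finding, warm-started along the pressure grid.

#' Standard EDPVR pressure grid
#'
#' 100 equal loading steps from 0 to 30 mmHg, i.e. p_k = 0.3 k mmHg for
#' k = 1..100.
#' @return Numeric vector of 100 pressures (mmHg).
#' @export
pressure_grid <- function() 0.3 * seq_len(100)

#' End-diastolic pressure-volume relationship container
#'
#' @param pressures Pressures (mmHg), strictly increasing and positive.
#' @param volumes LV cavity volumes (ul), strictly increasing, all > `V0`.
#' @param V0 Unloaded cavity volume (ul).
#' @return An object of class `edpvr`.
#' @export
edpvr <- function(pressures, volumes, V0) {
  if (length(pressures) != length(volumes))
    stop("pressures and volumes must have equal length")
  if (any(diff(pressures) <= 0) || any(pressures <= 0))
    stop("pressure grid must be positive and strictly increasing")
  if (any(diff(volumes) <= 0)) stop("volumes must be strictly increasing")
  if (any(volumes <= V0)) stop("all loaded volumes must exceed V0")
  structure(list(pressures = pressures, volumes = volumes, V0 = V0),
            class = "edpvr")
}

# per-layer quadrature rule over the reference wall [R_i, R_o]:
# layers equally spaced in reference radius, fiber angle constant per layer
.wall_quadrature <- function(cyl, fibers, n_gauss = 8) {
  nl <- fibers$n_layers
  gl <- gauss_legendre(n_gauss)
  edges <- seq(cyl$R_i, cyl$R_o, length.out = nl + 1)
  R <- c(); w <- c(); alpha <- c()
  for (m in seq_len(nl)) {
    h <- (edges[m + 1] - edges[m]) / 2
    R <- c(R, edges[m] + h * (gl$nodes + 1))
    w <- c(w, gl$weights * h)
    alpha <- c(alpha, rep(fibers$layer_angles[m], n_gauss))
  }
  list(R = R, w = w, cos2a = cos(alpha)^2, sin2a = sin(alpha)^2)
}

# luminal pressure (kPa) sustained at deformed inner radius r_i
.pressure_at <- function(r_i, cyl, quad, params) {
  r2 <- r_i^2 + quad$R^2 - cyl$R_i^2
  lt2 <- r2 / quad$R^2
  lr2 <- quad$R^2 / r2
  I1 <- lt2 + lr2 + 1
  I4f <- lt2 * quad$cos2a + quad$sin2a
  dsig <- params$a * exp_clamped(params$b * (I1 - 3)) * (lt2 - lr2) +
    2 * params$a_f * (I4f - 1) *
      exp_clamped(params$b_f * (I4f - 1)^2) * lt2 * quad$cos2a
  sum(quad$w * dsig * quad$R / r2)
}

#' Inflate the equivalent cylinder to produce an EDPVR
#'
#' Solves the radial equilibrium equation for the deformed inner radius at
#' each pressure of the grid (converted internally to kPa), with the base
#' fixed axially (lambda_z = 1) and exact incompressibility. Root finding
#' is bracketed and warm-started from the previous load step; the bracket
#' is capped at 10 R_i.
#'
#' @param cyl A `cylinder_model`.
#' @param fibers A `fiber_architecture`.
#' @param params A [material_params()] object.
#' @param grid Pressure grid in mmHg (default [pressure_grid()]).
#' @param n_gauss Gauss-Legendre points per fiber layer (default 8).
#' @return An [edpvr()] object; `V0 = pi R_i^2 L` exactly at zero load.
#' @export
inflate <- function(cyl, fibers, params, grid = pressure_grid(), n_gauss = 8) {
  if (any(diff(grid) <= 0) || any(grid <= 0))
    stop("pressure grid must be positive and strictly increasing")
  quad <- .wall_quadrature(cyl, fibers, n_gauss)
  P_kPa <- mmHg_to_kPa(grid)
  r_max <- 10 * cyl$R_i
  r_prev <- cyl$R_i
  r_i <- numeric(length(grid))
  for (k in seq_along(grid)) {
    f <- function(r) .pressure_at(r, cyl, quad, params) - P_kPa[k]
    lo <- r_prev
    hi <- min(r_prev * 1.05 + 1e-6, r_max)
    while (f(hi) < 0) {
      if (hi >= r_max)
        stop("inflation root not bracketed within 10 R_i")
      hi <- min(hi * 1.3, r_max)
    }
    r_i[k] <- stats::uniroot(f, c(lo, hi), tol = 1e-11 * cyl$R_i)$root
    r_prev <- r_i[k]
  }
  edpvr(grid, pi * r_i^2 * cyl$L, V0 = pi * cyl$R_i^2 * cyl$L)
}

# transmural stress state on a fine reference-radius grid at solved r_i
.stress_profile <- function(r_i, cyl, fibers, params, n_fine = 200) {
  nl <- fibers$n_layers
  edges <- seq(cyl$R_i, cyl$R_o, length.out = nl + 1)
  per <- ceiling(n_fine / nl)
  dR <- (cyl$R_o - cyl$R_i) / (nl * per)        # uniform cell width
  R <- c(); alpha <- c()
  for (m in seq_len(nl)) {
    R <- c(R, edges[m] + (seq_len(per) - 0.5) * dR)  # cell midpoints
    alpha <- c(alpha, rep(fibers$layer_angles[m], per))
  }
  r2 <- r_i^2 + R^2 - cyl$R_i^2
  lt2 <- r2 / R^2; lr2 <- R^2 / r2
  I1 <- lt2 + lr2 + 1
  ca <- cos(alpha); sa <- sin(alpha)
  I4f <- lt2 * ca^2 + sa^2
  mat <- params$a * exp_clamped(params$b * (I1 - 3))
  fib <- 2 * params$a_f * (I4f - 1) * exp_clamped(params$b_f * (I4f - 1)^2)
  dsig <- mat * (lt2 - lr2) + fib * lt2 * ca^2
  # sigma_rr(R) = -P + int_{R_i}^{R} dsig * Rref / r^2 dRref  (midpoint rule;
  # the full-wall integral of the same integrand equals P at equilibrium)
  g <- dsig * R / r2
  P_total <- sum(g * dR)
  sigma_rr <- -P_total + cumsum(g * dR) - g * dR / 2
  p <- mat * lr2 - sigma_rr
  # deformed fiber f = (0, lt cos a, sin a) since lambda_z = 1
  f2 <- sqrt(lt2) * ca; f3 <- sa
  s_tt <- mat * lt2 - p + fib * f2^2
  s_zz <- mat - p + fib * f3^2
  s_tz <- fib * f2 * f3
  sigma_ff <- (s_tt * f2^2 + s_zz * f3^2 + 2 * s_tz * f2 * f3) / I4f
  list(R = R, E_ff = (I4f - 1) / 2, sigma_ff = sigma_ff)
}

#' Fiber stress-strain curve along the inflation
#'
#' At each pressure of the grid, evaluates the transmural profile of the
#' fiber-direction Cauchy stress sigma_ff and Green-Lagrange fiber strain
#' E_ff = (I4f - 1)/2, and records the transmural maximum of sigma_ff with
#' the fiber strain at that location.
#'
#' @inheritParams inflate
#' @return A data.frame with columns `pressure_mmHg`, `E_ff`, `sigma_ff_max`.
#' @export
fiber_stress_curve <- function(cyl, fibers, params, grid = pressure_grid(),
                               n_gauss = 8) {
  curve <- inflate(cyl, fibers, params, grid, n_gauss)
  r_i <- sqrt(curve$volumes / (pi * cyl$L))
  out <- data.frame(pressure_mmHg = grid, E_ff = NA_real_,
                    sigma_ff_max = NA_real_)
  for (k in seq_along(grid)) {
    prof <- .stress_profile(r_i[k], cyl, fibers, params)
    j <- which.max(prof$sigma_ff)
    out$E_ff[k] <- prof$E_ff[j]
    out$sigma_ff_max[k] <- prof$sigma_ff[j]
  }
  out
}

#' Inverse Levenberg-Marquardt fit of material constants to a target EDPVR
#'
#' Least squares on the volume residuals V_model(p_k) - V_target(p_k) over
#' the target pressure grid, with the free parameters log-transformed for
#' positivity. Convergence when the relative step falls below 1e-8 or the
#' relative residual change below 1e-10 (200 iterations maximum).
#'
#' @param target An [edpvr()] object.
#' @param cyl,fibers Geometry and fiber architecture for the forward model.
#' @param free Character vector naming the free parameters, a subset of
#'   `c("a", "b", "a_f", "b_f")`.
#' @param init Named numeric starting values for the free parameters.
#' @param fixed Named numeric values for the remaining parameters.
#' @param n_gauss Quadrature points per layer.
#' @return A `fit_result` list: `estimates`, `rms_residual` (ul),
#'   `n_iterations`, `converged`, `init`.
#' @export
inverse_fit <- function(target, cyl, fibers, free = c("a_f", "b_f"),
                        init, fixed = c(a = 0.22, b = 1.62), n_gauss = 8) {
  stopifnot(all(free %in% c("a", "b", "a_f", "b_f")))
  init <- init[free]
  if (any(is.na(init))) stop("init must name every free parameter")
  all_names <- c("a", "b", "a_f", "b_f")
  resid_fun <- function(logpar) {
    vals <- exp(pmin(pmax(logpar, -50), 50))
    if (any(!is.finite(vals) | vals <= 0))
      return(rep(1e6, length(target$volumes)))
    pv <- c(stats::setNames(vals, free), fixed)[all_names]
    pr <- material_params(pv[["a_f"]], pv[["b_f"]], a = pv[["a"]], b = pv[["b"]])
    sim <- tryCatch(inflate(cyl, fibers, pr, target$pressures, n_gauss),
                    error = function(e) NULL)
    if (is.null(sim)) return(rep(1e6, length(target$volumes)))
    sim$volumes - target$volumes
  }
  fit <- minpack.lm::nls.lm(
    par = log(as.numeric(init)), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                         ptol = 1e-8, gtol = 0))
  est <- stats::setNames(exp(fit$par), free)
  structure(list(estimates = est,
                 rms_residual = sqrt(mean(fit$fvec^2)),
                 n_iterations = fit$niter,
                 converged = fit$info %in% 1:4,
                 init = init),
            class = "fit_result")
}

#' Multi-start identifiability diagnostic for a parameter pair
#'
#' Repeats [inverse_fit()] from several starting points. Starts whose
#' final residual exceeds the tolerance are optimizer failures (e.g. the
#' flat b_f -> 0 subspace) and carry no evidence either way; they are
#' reported but excluded from the uniqueness assessment. The pair is
#' classified identifiable when all successful fits agree within 1%
#' (maximum pairwise relative distance); two successful fits with grossly
#' different estimates demonstrate non-identifiability.
#'
#' @inheritParams inverse_fit
#' @param pair Character vector of length 2 naming the free parameters.
#' @param inits List of named numeric starting values (>= 2 for a
#'   meaningful diagnosis; a single start is trivially "identifiable" and
#'   warned about).
#' @param resid_tol Residual tolerance separating successful fits from
#'   optimizer failures, as a fraction of the mean target volume (default
#'   0.005, i.e. 0.5% volume RMS).
#' @return A list: `fits`, `estimates`, `success` (logical per start),
#'   `max_rel_spread` (over successful fits), `max_rms_residual`,
#'   `identifiable`.
#' @export
identifiability_report <- function(target, cyl, fibers, pair, inits,
                                   fixed = c(a = 0.22, b = 1.62),
                                   resid_tol = 0.005, n_gauss = 8) {
  if (length(inits) < 2)
    warning("single initialization: identifiability is trivially satisfied")
  fits <- lapply(inits, function(ini)
    inverse_fit(target, cyl, fibers, free = pair, init = ini,
                fixed = fixed, n_gauss = n_gauss))
  est <- do.call(rbind, lapply(fits, function(f) f$estimates))
  resid <- vapply(fits, function(f) f$rms_residual, 0)
  tol_abs <- resid_tol * mean(target$volumes)
  success <- resid < tol_abs
  ok <- which(success)
  spread <- 0
  if (length(ok) > 1) {
    for (i in ok[-length(ok)])
      for (j in ok[ok > i])
        spread <- max(spread, abs(est[i, ] - est[j, ]) / pmin(est[i, ], est[j, ]))
  }
  if (!any(success))
    warning("no start reached the residual tolerance; pair unassessable")
  list(fits = fits, estimates = est, success = success,
       max_rel_spread = spread, max_rms_residual = max(resid),
       identifiable = any(success) && spread < 0.01)
}

#' Write / read an EDPVR as two-column delimited text
#'
#' Header `pressure_mmHg,volume_ul`; the unloaded volume is stored in a
#' leading comment line `# V0_ul=<value>`.
#' @param curve An [edpvr()] object.
#' @param file Path.
#' @export
write_edpvr <- function(curve, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# V0_ul=%.17g", curve$V0), con)
  writeLines("pressure_mmHg,volume_ul", con)
  writeLines(sprintf("%.17g,%.17g", curve$pressures, curve$volumes), con)
  invisible(file)
}

#' @rdname write_edpvr
#' @export
read_edpvr <- function(file) {
  lines <- readLines(file)
  v0 <- NA_real_
  meta <- grepl("^#", lines)
  if (any(meta)) {
    m <- regmatches(lines[meta][1], regexec("V0_ul=([0-9.eE+-]+)", lines[meta][1]))[[1]]
    if (length(m) == 2) v0 <- as.numeric(m[2])
  }
  d <- utils::read.csv(text = paste(lines[!meta], collapse = "\n"))
  if (is.na(v0)) v0 <- d$volume_ul[1] * 0.999  # fallback: just below first point
  edpvr(d$pressure_mmHg, d$volume_ul, V0 = v0)
}
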