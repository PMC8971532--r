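# Reduced Holzapfel-Ogden transversely isotropic hyperelastic model of
# passive myocardium:
#
#   Psi = a/(2b) exp[b(I1 - 3)] + a_f/(2 b_f) {exp[b_f (I4f - 1)^2] - 1}
#
# with isotropic ground-matrix constants (a, b) and fiber constants
# (a_f, b_f).  Only shear-free diagonal deformations with the fiber in the
# theta-z plane are needed anywhere in this package, so the deformation
# state is parameterized by the three principal stretches and the reference
# fiber helix angle.

#' Material constants of the reduced Holzapfel-Ogden model
#'
#' Four strictly positive constants: `a` (kPa) and `b` (dimensionless) for
#' the isotropic ground matrix, `a_f` (kPa) and `b_f` (dimensionless) for
#' the myofiber direction. Throughout the stiffness-estimation workflow the
#' matrix constants are fixed at the healthy-myocardium reference values
#' a = 0.22 kPa, b = 1.62 and only the fiber pair varies.
#'
#' @param a_f Fiber stress-like constant (kPa).
#' @param b_f Fiber exponent (dimensionless).
#' @param a Matrix stress-like constant (kPa); default 0.22.
#' @param b Matrix exponent (dimensionless); default 1.62.
#' @return An object of class `ho_params`.
#' @export
material_params <- function(a_f, b_f, a = 0.22, b = 1.62) {
  vals <- c(a = a, b = b, a_f = a_f, b_f = b_f)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all four material constants must be strictly positive and finite")
  structure(as.list(vals), class = "ho_params")
}

#' @export
print.ho_params <- function(x, ...) {
  cat(sprintf("Holzapfel-Ogden (reduced): a = %g kPa, b = %g, a_f = %g kPa, b_f = %g\n",
              x$a, x$b, x$a_f, x$b_f))
  invisible(x)
}

#' Deformation invariants of a shear-free stretch state
#'
#' For principal stretches (lambda_r, lambda_t, lambda_z) and a fiber lying
#' in the theta-z plane at helix angle `alpha` from the circumferential
#' direction: I1 = sum(lambda_i^2), I4f = lambda_t^2 cos^2(alpha) +
#' lambda_z^2 sin^2(alpha).
#'
#' @param lambda_r,lambda_t,lambda_z Principal stretches (> 0).
#' @param alpha Fiber helix angle (radians).
#' @return A list with elements `I1` and `I4f`.
#' @export
invariants_from_stretches <- function(lambda_r, lambda_t, lambda_z, alpha) {
  if (any(c(lambda_r, lambda_t, lambda_z) <= 0))
    stop("principal stretches must be strictly positive")
  list(I1 = lambda_r^2 + lambda_t^2 + lambda_z^2,
       I4f = lambda_t^2 * cos(alpha)^2 + lambda_z^2 * sin(alpha)^2)
}

#' Deformation state for the diagonal (shear-free) case
#'
#' Bundles the principal stretches, helix angle, derived invariants and the
#' hydrostatic pressure. Incompressibility (J = 1) must hold to within 1e-12.
#'
#' @inheritParams invariants_from_stretches
#' @param p Hydrostatic pressure (kPa).
#' @return An object of class `deformation_state`.
#' @export
deformation_state <- function(lambda_r, lambda_t, lambda_z, alpha, p = 0) {
  inv <- invariants_from_stretches(lambda_r, lambda_t, lambda_z, alpha)
  J <- lambda_r * lambda_t * lambda_z
  if (abs(J - 1) > 1e-12)
    stop(sprintf("incompressibility violated: J = %.15g", J))
  structure(list(lambda_r = lambda_r, lambda_t = lambda_t, lambda_z = lambda_z,
                 alpha = alpha, I1 = inv$I1, I4f = inv$I4f, J = J, p = p),
            class = "deformation_state")
}

# Energy density as a function of the invariants alone (no incompressibility
# constraint) -- used for finite-difference stress checks.
#' Strain-energy density from invariants
#'
#' Evaluates the reduced Holzapfel-Ogden energy at given (I1, I4f). The
#' printed energy form is nonzero at the reference state (the matrix term
#' equals a/(2b) at I1 = 3), so callers that need an energy measured from
#' the reference should subtract `psi_ho(3, 1, params)`.
#'
#' @param I1 First invariant.
#' @param I4f Fiber invariant (squared fiber stretch).
#' @param params A [material_params()] object.
#' @return Energy density (kPa).
#' @export
psi_ho <- function(I1, I4f, params) {
  params$a / (2 * params$b) * exp_clamped(params$b * (I1 - 3)) +
    params$a_f / (2 * params$b_f) *
      (exp_clamped(params$b_f * (I4f - 1)^2) - 1)
}

#' Strain energy of a deformation state
#'
#' @param state A [deformation_state()].
#' @param params A [material_params()] object.
#' @return A list with `psi` (the energy as printed, kPa) and `psi_rel`
#'   (the energy measured from the reference state, so that
#'   `psi_rel = 0` at identity deformation).
#' @export
strain_energy <- function(state, params) {
  psi <- psi_ho(state$I1, state$I4f, params)
  list(psi = psi, psi_rel = psi - psi_ho(3, 1, params))
}

#' Cauchy stress of a diagonal deformation state
#'
#' sigma = a exp[b(I1-3)] B - p I + 2 a_f (I4f - 1) exp[b_f (I4f-1)^2] f x f
#' with B = diag(lambda_r^2, lambda_t^2, lambda_z^2) and deformed fiber
#' f = (0, lambda_t cos(alpha), lambda_z sin(alpha)). The fiber term is
#' applied for any I4f (no tension-only switch); in the inflation loading
#' used throughout, I4f >= 1 so the distinction is inert.
#'
#' @param state A [deformation_state()] (J = 1 required).
#' @param params A [material_params()] object.
#' @return A list with `sigma` (named vector: rr, tt, zz components, kPa;
#'   the theta-z shear from the fiber term is reported as `sigma_tz`) and
#'   `sigma_ff`, the normal stress along the deformed fiber direction.
#' @export
cauchy_stress <- function(state, params) {
  if (abs(state$J - 1) > 1e-12) stop("cauchy_stress requires J = 1")
  mat <- params$a * exp_clamped(params$b * (state$I1 - 3))
  fib <- 2 * params$a_f * (state$I4f - 1) *
    exp_clamped(params$b_f * (state$I4f - 1)^2)
  ca <- cos(state$alpha); sa <- sin(state$alpha)
  f <- c(0, state$lambda_t * ca, state$lambda_z * sa)
  s_rr <- mat * state$lambda_r^2 - state$p
  s_tt <- mat * state$lambda_t^2 - state$p + fib * f[2]^2
  s_zz <- mat * state$lambda_z^2 - state$p + fib * f[3]^2
  s_tz <- fib * f[2] * f[3]
  # unit deformed-fiber direction; |f|^2 = I4f
  nf2 <- state$I4f
  sigma_ff <- if (nf2 > 0) {
    (s_tt * f[2]^2 + s_zz * f[3]^2 + 2 * s_tz * f[2] * f[3]) / nf2
  } else s_rr
  list(sigma = c(rr = s_rr, tt = s_tt, zz = s_zz, tz = s_tz),
       sigma_ff = sigma_ff)
}

#' Equibiaxial trace of the first Piola-Kirchhoff stress
#'
#' For in-plane equibiaxial stretch (lambda, lambda, lambda^-2) with the
#' fiber in the loading plane, plane stress through the thickness fixes the
#' hydrostatic pressure p = a exp[b(I1-3)] lambda^-4, and the trace
#' P11 + P22 = (sigma11 + sigma22)/lambda follows. The result is
#' independent of the in-plane fiber angle because I4f = lambda^2 for any
#' in-plane fiber under equibiaxial stretch.
#'
#' @param lambda In-plane stretch, >= 1 (vectorized).
#' @param params A [material_params()] object.
#' @return P11 + P22 (kPa).
#' @export
equibiaxial_trace <- function(lambda, params) {
  if (any(lambda < 1)) stop("equibiaxial stretch must be >= 1")
  I1 <- 2 * lambda^2 + lambda^-4
  mat <- params$a * exp_clamped(params$b * (I1 - 3))
  p <- mat * lambda^-4
  I4f <- lambda^2
  fib <- 2 * params$a_f * (I4f - 1) * exp_clamped(params$b_f * (I4f - 1)^2)
  s11_plus_s22 <- 2 * mat * lambda^2 - 2 * p + fib * lambda^2
  s11_plus_s22 / lambda
}

#' Biaxial stress-stretch data
#'
#' @param stretch Strictly increasing stretches (>= 1).
#' @param trace_P_kPa Measured P11 + P22 (kPa), same length.
#' @return An object of class `biaxial_data`.
#' @export
biaxial_data <- function(stretch, trace_P_kPa) {
  if (length(stretch) != length(trace_P_kPa))
    stop("stretch and trace_P_kPa must have equal length")
  if (any(diff(stretch) <= 0)) stop("stretches must be strictly increasing")
  if (any(stretch < 1)) stop("stretches must be >= 1")
  structure(data.frame(stretch = stretch, trace_P_kPa = trace_P_kPa),
            class = c("biaxial_data", "data.frame"))
}

#' Read / write biaxial data (two-column delimited text)
#'
#' Header `stretch,trace_P_kPa`.
#' @param file Path.
#' @export
read_biaxial <- function(file) {
  d <- utils::read.csv(file)
  biaxial_data(d$stretch, d$trace_P_kPa)
}

#' @rdname read_biaxial
#' @param data A [biaxial_data()] object.
#' @export
write_biaxial <- function(data, file) {
  utils::write.csv(as.data.frame(data), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Fit fiber constants to equibiaxial stress-stretch data
#'
#' Nonlinear least squares for (a_f, b_f) with the matrix constants fixed,
#' minimizing the residual between [equibiaxial_trace()] and the measured
#' trace of the first Piola-Kirchhoff stress. Parameters are optimized on
#' the log scale to enforce positivity, with a multi-start over the four
#' corners of the sampling range (a_f in 0.01..100 kPa, b_f in 0.01..20) to
#' avoid local minima.
#'
#' @param data A [biaxial_data()] object (>= 3 points with stretch > 1).
#' @param a,b Fixed matrix constants.
#' @param starts Optional matrix of (a_f, b_f) starting points, one per row.
#' @return A list with `a_f`, `b_f`, `rms_residual` (kPa), `converged`, and
#'   the full `ho_params` object.
#' @export
fit_biaxial <- function(data, a = 0.22, b = 1.62, starts = NULL) {
  d <- as.data.frame(data)
  d <- d[d$stretch > 1, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 data points with stretch > 1")
  if (all(data$stretch == 1)) stop("degenerate data: all stretches equal 1")
  if (is.null(starts))
    starts <- as.matrix(expand.grid(a_f = c(0.02, 50), b_f = c(0.02, 10)))
  resid_fun <- function(logpar) {
    pr <- material_params(exp(logpar[1]), exp(logpar[2]), a = a, b = b)
    equibiaxial_trace(d$stretch, pr) - d$trace_P_kPa
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(as.numeric(starts[i, ])), fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss)
      best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) stop("biaxial fit failed from every starting point")
  est <- exp(best$fit$par)
  conv <- best$fit$info %in% 1:4
  if (!conv)
    warning("biaxial fit did not meet convergence criteria; returning last iterate")
  list(a_f = est[1], b_f = est[2],
       rms_residual = sqrt(best$ss / nrow(d)),
       converged = conv,
       params = material_params(est[1], est[2], a = a, b = b))
}
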