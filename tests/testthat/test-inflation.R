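# Semi-analytic cylinder inflation: unloaded state, scaling laws,
# small-strain limit, refinement stability, fiber stress and the inverse
# Levenberg-Marquardt fitter.

coarse_grid <- function(n = 20) seq(1.5, 30, length.out = n)

test_that("the unloaded state and low-pressure limit are exact", {
  cyl <- fixture_cylinder()
  fib <- fixture_fibers()
  pr <- fixture_params()
  expect_error(inflate(cyl, fib, pr, grid = c(0, 1)), "positive")
  cv <- inflate(cyl, fib, pr, grid = c(1e-8, 1))
  expect_equal(cv$V0, pi * cyl$R_i^2 * cyl$L)
  expect_equal(cv$volumes[1], cv$V0, tolerance = 1e-6)
  expect_true(all(diff(inflate(cyl, fib, pr)$volumes) > 0))
})

test_that("pressure scaling by c with (c a, c a_f) leaves volumes unchanged", {
  cyl <- fixture_cylinder()
  fib <- fixture_fibers()
  pr <- material_params(a_f = 2.3, b_f = 4, a = 0.22, b = 1.62)
  base <- inflate(cyl, fib, pr, grid = coarse_grid())
  for (c_scale in c(0.2, 5)) {
    pr2 <- material_params(c_scale * pr$a_f, pr$b_f, a = c_scale * pr$a,
                           b = pr$b)
    scaled <- inflate(cyl, fib, pr2, grid = c_scale * coarse_grid())
    expect_equal(scaled$volumes, base$volumes, tolerance = 1e-9)
  }
})

test_that("small-strain volume slope matches the thick-wall closed form", {
  # alpha ~ 0, single layer: dV/dP = pi L / ((a + a_f)(1/R_i^2 - 1/R_o^2))
  cyl <- fixture_cylinder()
  fib <- fiber_layers(1e-9, -1e-9, 1)
  pr <- fixture_params()
  p_tiny <- 0.02  # mmHg
  cv <- inflate(cyl, fib, pr, grid = c(p_tiny / 2, p_tiny))
  slope <- (cv$volumes[2] - cv$V0) / mmHg_to_kPa(p_tiny)
  closed <- pi * cyl$L / ((pr$a + pr$a_f) * (1 / cyl$R_i^2 - 1 / cyl$R_o^2))
  expect_equal(slope, closed, tolerance = 0.01)
})

test_that("quadrature and step refinement change volumes by < 0.1%", {
  cyl <- fixture_cylinder()
  fib <- fixture_fibers()
  pr <- material_params(a_f = 0.5, b_f = 8)
  grid <- pressure_grid()
  v1 <- inflate(cyl, fib, pr, grid, n_gauss = 8)$volumes
  fine_grid <- sort(c(grid, grid - 0.15))
  v2 <- inflate(cyl, fib, pr, fine_grid, n_gauss = 16)$volumes
  v2_on_grid <- v2[match(grid, fine_grid)]
  expect_lt(max(abs(v2_on_grid - v1) / v1), 1e-3)
})

test_that("stiffening the fibers reduces the volume at every pressure", {
  cyl <- fixture_cylinder()
  fib <- fixture_fibers()
  soft <- inflate(cyl, fib, material_params(1, 2), coarse_grid())
  stiff <- inflate(cyl, fib, material_params(4, 2), coarse_grid())
  expect_true(all(stiff$volumes < soft$volumes))
})

test_that("fiber stress starts at zero, rises monotonically, and needs fibers", {
  cyl <- fixture_cylinder()
  fib <- fixture_fibers()
  # reference state: sigma_ff = 0, E_ff = 0 exactly
  prof0 <- myostiff:::.stress_profile(cyl$R_i, cyl, fib, fixture_params())
  expect_equal(max(abs(prof0$sigma_ff)), 0, tolerance = 1e-12)
  expect_equal(max(abs(prof0$E_ff)), 0, tolerance = 1e-14)
  set.seed(8)
  for (i in 1:5) {
    pr <- material_params(exp(runif(1, log(0.1), log(50))), runif(1, 0.5, 10))
    sc <- fiber_stress_curve(cyl, fib, pr, coarse_grid(10))
    expect_true(all(diff(sc$sigma_ff_max) > -1e-10))
    expect_true(all(sc$E_ff >= 0))
  }
  # a_f -> 0: the stress equals the matrix-only fiber projection
  pr_lo <- material_params(1e-12, 1)
  pr_hi <- material_params(1e-6, 1)
  s_lo <- fiber_stress_curve(cyl, fib, pr_lo, c(5, 10))
  s_hi <- fiber_stress_curve(cyl, fib, pr_hi, c(5, 10))
  expect_equal(s_lo$sigma_ff_max, s_hi$sigma_ff_max, tolerance = 1e-5)
})

test_that("inverse fit recovers fiber constants from any spread start", {
  cyl <- fixture_cylinder()
  fib <- fixture_fibers()
  truth <- material_params(a_f = 3.5, b_f = 6)
  target <- inflate(cyl, fib, truth, coarse_grid())
  # spread starts across both orders of magnitude; every start that
  # achieves a good fit must land on the same (unique) estimate, and the
  # well-posed region must be reached from most starts
  inits <- list(c(a_f = 0.05, b_f = 1), c(a_f = 0.05, b_f = 15),
                c(a_f = 80, b_f = 1), c(a_f = 80, b_f = 15),
                c(a_f = 1, b_f = 5))
  n_good <- 0
  for (ini in inits) {
    fit <- inverse_fit(target, cyl, fib, free = c("a_f", "b_f"), init = ini)
    if (fit$rms_residual < 0.005 * mean(target$volumes)) {
      n_good <- n_good + 1
      expect_equal(unname(fit$estimates[["a_f"]]), 3.5, tolerance = 1e-4)
      expect_equal(unname(fit$estimates[["b_f"]]), 6, tolerance = 1e-4)
    }
  }
  expect_gte(n_good, 3)
})

test_that("a fit started at the truth terminates immediately", {
  cyl <- fixture_cylinder()
  fib <- fixture_fibers()
  truth <- material_params(a_f = 2, b_f = 3)
  target <- inflate(cyl, fib, truth, coarse_grid(10))
  fit <- inverse_fit(target, cyl, fib, init = c(a_f = 2, b_f = 3))
  expect_lt(fit$rms_residual, 1e-8 * mean(target$volumes))
  expect_lte(fit$n_iterations, 3)
})

test_that("identifiability report classifies a unique pair as identifiable", {
  cyl <- fixture_cylinder()
  fib <- fixture_fibers()
  target <- inflate(cyl, fib, material_params(5, 4), coarse_grid(15))
  rep_ok <- identifiability_report(
    target, cyl, fib, pair = c("a_f", "b_f"),
    inits = list(c(a_f = 0.1, b_f = 0.1), c(a_f = 50, b_f = 12)))
  expect_true(rep_ok$identifiable)
  expect_lt(rep_ok$max_rel_spread, 0.01)
  expect_warning(
    identifiability_report(target, cyl, fib, pair = c("a_f", "b_f"),
                           inits = list(c(a_f = 1, b_f = 1))),
    "single initialization")
})

test_that("EDPVR containers validate and round-trip through text", {
  expect_error(edpvr(c(1, 2), c(10, 9), V0 = 5), "increasing")
  expect_error(edpvr(c(1, 2), c(4, 9), V0 = 5), "exceed V0")
  cv <- inflate(fixture_cylinder(), fixture_fibers(), fixture_params(),
                coarse_grid(10))
  f <- withr::local_tempfile(fileext = ".csv")
  write_edpvr(cv, f)
  back <- read_edpvr(f)
  expect_equal(back$pressures, cv$pressures)
  expect_equal(back$volumes, cv$volumes)
  expect_equal(back$V0, cv$V0)
})
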