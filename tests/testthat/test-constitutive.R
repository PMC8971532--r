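# Reduced Holzapfel-Ogden model: invariants, energy, stress, equibiaxial
# response and biaxial parameter recovery.

test_that("invariants match their definitions", {
  expect_equal(invariants_from_stretches(1, 1, 1, 0.7),
               list(I1 = 3, I4f = 1))
  # alpha = 0: I4f = lambda_theta^2
  inv <- invariants_from_stretches(1 / 1.21, 1.1, 1.1, 0)
  expect_equal(inv$I4f, 1.21)
  # frozen symbolic-algebra oracle at alpha = pi/4
  inv <- invariants_from_stretches(0.826, 1.1, 1.1, pi / 4)
  expect_equal(inv$I1, 3.102276, tolerance = 1e-14)
  expect_equal(inv$I4f, 1.21, tolerance = 1e-14)
  expect_error(invariants_from_stretches(-1, 1, 1, 0), "positive")
})

test_that("strain energy matches the closed form and vanishes at reference", {
  ref <- deformation_state(1, 1, 1, 0.3)
  pr <- material_params(0.806, 0.470)
  en <- strain_energy(ref, pr)
  expect_equal(en$psi_rel, 0)
  expect_gt(en$psi, 0)       # printed form is nonzero at reference
  # frozen oracle at (I1, I4f) = (3.2, 1.21), equibiaxial-test constants
  expect_equal(psi_ho(3.2, 1.21, pr), 0.11184122149970968, tolerance = 1e-13)
  # a_f -> 0 limit kills the fiber term
  pr0 <- material_params(1e-12, 0.470)
  expect_equal(psi_ho(3.2, 1.4, pr0), psi_ho(3.2, 1.0, pr0), tolerance = 1e-10)
})

test_that("stress is zero at reference with p = a and linear in (a, a_f)", {
  pr <- fixture_params()
  st <- deformation_state(1, 1, 1, 0.5, p = pr$a)
  s <- cauchy_stress(st, pr)
  expect_equal(unname(s$sigma), c(0, 0, 0, 0))
  expect_equal(s$sigma_ff, 0)
  # scaling (a, a_f) -> (c a, c a_f) at p = 0 scales every component by c
  st2 <- deformation_state(1 / (1.2 * 1.05), 1.2, 1.05, 0.4, p = 0)
  base <- cauchy_stress(st2, pr)
  scaled <- cauchy_stress(st2, material_params(3 * pr$a_f, pr$b_f,
                                               a = 3 * pr$a, b = pr$b))
  expect_equal(scaled$sigma, 3 * base$sigma, tolerance = 1e-14)
  expect_equal(scaled$sigma_ff, 3 * base$sigma_ff, tolerance = 1e-14)
})

test_that("deviatoric stress equals finite differences of the energy", {
  # sigma_ii + p = lambda_i dPsi/dlambda_i for the unconstrained energy
  pr <- material_params(0.9, 3.1, a = 0.22, b = 1.62)
  for (st in random_states(100, seed = 42)) {
    s <- cauchy_stress(st, pr)
    lam <- c(st$lambda_r, st$lambda_t, st$lambda_z)
    for (i in 1:3) {
      h <- 1e-6 * lam[i]
      lp <- lam; lp[i] <- lam[i] + h
      lm <- lam; lm[i] <- lam[i] - h
      ip <- invariants_from_stretches(lp[1], lp[2], lp[3], st$alpha)
      im <- invariants_from_stretches(lm[1], lm[2], lm[3], st$alpha)
      dpsi <- (psi_ho(ip$I1, ip$I4f, pr) - psi_ho(im$I1, im$I4f, pr)) / (2 * h)
      got <- s$sigma[[i]] + st$p
      want <- lam[i] * dpsi
      expect_lt(abs(got - want) / max(abs(got), abs(want), 1e-6), 1e-6)
    }
  }
})

test_that("equibiaxial trace matches the symbolic oracle and is angle-invariant", {
  pr <- material_params(0.806, 0.470)
  expect_equal(equibiaxial_trace(1, pr), 0)
  # frozen full-tensor symbolic oracle (P = J sigma F^-T, plane stress)
  expect_equal(equibiaxial_trace(1.1, pr), 0.62924869246271670,
               tolerance = 1e-13)
  expect_error(equibiaxial_trace(0.9, pr), ">= 1")
  # cross-check against cauchy_stress + plane-stress p + Piola transform
  lam <- 1.15
  st <- deformation_state(lam^-2, lam, lam, alpha = pi / 2, p = 0)
  s0 <- cauchy_stress(st, pr)
  p_ps <- s0$sigma[["rr"]]            # enforce sigma_rr = 0 (thickness dir)
  st <- deformation_state(lam^-2, lam, lam, alpha = pi / 2, p = p_ps)
  s <- cauchy_stress(st, pr)
  expect_equal((s$sigma[["tt"]] + s$sigma[["zz"]]) / lam,
               equibiaxial_trace(lam, pr), tolerance = 1e-12)
})

test_that("biaxial fit recovers known constants from noiseless curves", {
  lam <- seq(1.02, 1.25, length.out = 12)
  for (truth in list(c(0.806, 0.470), c(34.261, 11.275))) {
    pr <- material_params(truth[1], truth[2])
    d <- biaxial_data(lam, equibiaxial_trace(lam, pr))
    fit <- fit_biaxial(d)
    expect_true(fit$converged)
    expect_equal(fit$a_f, truth[1], tolerance = 1e-6)
    expect_equal(fit$b_f, truth[2], tolerance = 1e-6)
    expect_lt(fit$rms_residual, 1e-8 * max(d$trace_P_kPa))
  }
})

test_that("biaxial fit recovers 20 random draws from the sampling ranges", {
  set.seed(19)
  lam <- seq(1.01, 1.2, length.out = 15)
  for (i in 1:20) {
    a_f <- exp(runif(1, log(0.01), log(100)))
    b_f <- exp(runif(1, log(0.01), log(20)))
    pr <- material_params(a_f, b_f)
    tr <- equibiaxial_trace(lam, pr)
    if (max(tr) > 1e5) next        # outside any measurable regime
    fit <- fit_biaxial(biaxial_data(lam, tr))
    expect_equal(fit$a_f, a_f, tolerance = 1e-4)
    expect_equal(fit$b_f, b_f, tolerance = 1e-4)
  }
})

test_that("degenerate biaxial data is rejected", {
  expect_error(fit_biaxial(biaxial_data(c(1, 1.01, 1.02), c(0, 0.1, 0.2))),
               "at least 3")
  expect_error(biaxial_data(c(1.1, 1.05), c(1, 2)), "increasing")
})

test_that("biaxial data round-trips through delimited text", {
  d <- biaxial_data(c(1.0, 1.1, 1.2), c(0, 0.63, 1.9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_biaxial(d, f)
  expect_equal(readLines(f)[1], "stretch,trace_P_kPa")
  expect_equal(as.data.frame(read_biaxial(f)), as.data.frame(d))
})
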