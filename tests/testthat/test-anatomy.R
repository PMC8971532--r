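# Idealized biventricular geometry: parent generation, resizing, feature
# extraction, fiber rule and the equivalent-cylinder reduction.

# constant-field ranges let exact solids be constructed for oracles
const_ranges <- function(R_epi, Z_epi, R_lv, Z_lv, sector = 1.5, tfrac = 0.4) {
  list(R_epi = c(R_epi, R_epi), Z_epi = c(Z_epi, Z_epi),
       R_lv = c(R_lv, R_lv), Z_lv = c(Z_lv, Z_lv),
       rv_sector = c(sector, sector), rv_thickness_frac = c(tfrac, tfrac))
}

test_that("parent generation is seeded and validates ranges", {
  expect_equal(unclass(make_parent(7)), unclass(make_parent(7)))
  expect_false(identical(make_parent(7)$R_epi, make_parent(8)$R_epi))
  p <- make_parent(1, const_ranges(4, 11, 2, 8.6))
  expect_equal(p$R_epi, 4)
  expect_equal(p$Z_lv, 8.6)
  bad <- parent_ranges(); bad$R_lv <- c(2.1, 1.9)
  expect_error(make_parent(1, bad), "inverted")
})

test_that("unloaded LV volume spans ~35 ul to about five times that", {
  parents <- make_parent_library(25, seed = 5)
  vols <- unlist(lapply(parents, function(p) {
    sapply(c(0.7, 1.6), function(f)
      geometric_features(resize(p, f_LV = f, f_RV = 1))[["LV_V"]])
  }))
  expect_gt(min(vols), 35 * 0.8)
  expect_lt(min(vols), 35 * 1.2)
  expect_gt(max(vols) / min(vols), 4)
  expect_lt(max(vols) / min(vols), 6)
})

test_that("resizing scales the LV cavity in-plane and preserves the epicardium", {
  p <- fixture_parent()
  f0 <- geometric_features(resize(p, 1, 1))
  expect_equal(f0, geometric_features(p))   # identity resize
  f1 <- geometric_features(resize(p, 1.1, 1))
  # X-Y isotropic scaling with fixed long axis: volume scales by f^2
  expect_equal(f1[["LV_V"]], 1.1^2 * f0[["LV_V"]], tolerance = 1e-12)
  epi_cols <- c(paste0("S_A", 1:6), "Epi_V", "Epi_A")
  expect_equal(f1[epi_cols], f0[epi_cols])
  expect_equal(geometric_features(resize(p, 1, 1.3))[c("LV_V", "LV_A")],
               f0[c("LV_V", "LV_A")])
  # near-touching parent: resize must refuse surface intersection
  tight <- make_parent(1, const_ranges(4, 11, 2.6, 8.6))
  expect_error(resize(tight, 1.6, 1), "intersect")
})

test_that("features recover closed-form solids in the hemisphere limit", {
  p <- make_parent(1, const_ranges(R_epi = 4, Z_epi = 4, R_lv = 2, Z_lv = 3))
  f <- geometric_features(p)
  expect_equal(f[["Epi_V"]], 2 / 3 * pi * 4^3, tolerance = 1e-9)
  # lateral (open-base) surface of a hemisphere
  expect_equal(f[["Epi_A"]], 2 * pi * 4^2, tolerance = 1e-6)
  expect_equal(f[["S_A1"]], pi * 4^2, tolerance = 1e-12)
  expect_equal(f[["LV_V"]], 2 / 3 * pi * 2^2 * 3, tolerance = 1e-9)
})

test_that("features agree with Monte-Carlo integration oracles", {
  set.seed(101)
  geom <- resize(make_parent(23), 1.25, 1.1)
  p <- geom$parent
  f <- geometric_features(geom)
  n <- 1e6
  # 3-D rejection oracle for the LV cavity volume
  z <- runif(n, 0, p$Z_lv); x <- runif(n, -p$R_lv * 1.25, p$R_lv * 1.25)
  y <- runif(n, -p$R_lv * 1.25, p$R_lv * 1.25)
  rlv <- 1.25 * p$R_lv * sqrt(pmax(0, 1 - (z / p$Z_lv)^2))
  mc_lv <- mean(x^2 + y^2 < rlv^2) * (2 * 1.25 * p$R_lv)^2 * p$Z_lv
  expect_equal(f[["LV_V"]], mc_lv, tolerance = 5e-3)
  # 1-D Monte-Carlo integration of the lateral-area integrand
  z <- runif(n, 0, p$Z_lv)
  s <- sqrt(pmax(1e-12, 1 - (z / p$Z_lv)^2))
  r <- 1.25 * p$R_lv * s
  dr <- -1.25 * p$R_lv * z / (p$Z_lv^2 * s)
  mc_area <- mean(2 * pi * r * sqrt(1 + dr^2)) * p$Z_lv
  expect_equal(f[["LV_A"]], mc_area, tolerance = 5e-3)
})

test_that("RV crescent quadrature agrees with Monte-Carlo on random geometries", {
  set.seed(77)
  for (i in 1:20) {
    geom <- resize(make_parent(300 + i), runif(1, 0.7, 1.6), runif(1, 0.7, 1.6))
    f <- geometric_features(geom)
    rv <- myostiff:::.rv_surfaces(geom)
    n <- 2e5
    z <- runif(n, 0, rv$z1)
    mc_v <- mean(rv$phi / 2 * (rv$r_out(z)^2 - rv$r_in(z)^2)) * rv$z1
    expect_equal(f[["RV_V"]], mc_v, tolerance = 5e-3)
    eps <- 1e-6
    darea <- function(rf) {
      rr <- rf(z)
      dd <- (rf(pmin(rv$z1, z + eps)) - rf(pmax(0, z - eps))) /
        (pmin(rv$z1, z + eps) - pmax(0, z - eps))
      mean(2 * pi * rv$phi / (2 * pi) * rr * sqrt(1 + dd^2)) * rv$z1
    }
    expect_equal(f[["RV_A"]], darea(rv$r_in) + darea(rv$r_out),
                 tolerance = 5e-3)
  }
})

test_that("slice areas are ordered and LV features increase with f_LV", {
  for (seed in 1:10) {
    p <- make_parent(seed + 40)
    f <- geometric_features(resize(p, runif(1, 0.7, 1.6), runif(1, 0.7, 1.6)))
    sa <- f[paste0("S_A", 1:6)]
    expect_true(all(diff(sa) < 0))
    expect_true(all(f > 0))
    expect_lt(f[["LV_V"]], f[["Epi_V"]])
  }
  p <- fixture_parent()
  lv <- t(sapply(seq(0.7, 1.6, length.out = 5), function(fl)
    geometric_features(resize(p, fl, 1))[c("LV_V", "LV_A")]))
  expect_true(all(diff(lv[, 1]) > 0))
  expect_true(all(diff(lv[, 2]) > 0))
})

test_that("fiber rule interpolates linearly at layer midpoints", {
  fb <- fiber_layers(pi / 3, -pi / 3, 4)
  expect_equal(fb$layer_angles, pi / 3 * c(0.75, 0.25, -0.25, -0.75))
  # antisymmetry about mid-wall when theta_endo = -theta_epi
  fb2 <- fiber_layers(0.8, -0.8, 6)
  expect_equal(fb2$layer_angles, -rev(fb2$layer_angles))
  expect_equal(fiber_layers(0.9, -0.3, 2)$layer_angles, c(0.6, 0))
  expect_error(fiber_layers(-0.1, -0.3), "theta_endo")
  expect_error(fiber_layers(0.5, 0.2), "theta_epi")
})

test_that("equivalent cylinder preserves lumen and wall volumes", {
  # direct inversion: LV_V = pi 10^2 15 with L = 15 gives R_i = 10
  feats <- c(LV_V = pi * 100 * 15, RV_V = 40, Epi_V = pi * 100 * 15 + 500 + 40)
  cyl <- equivalent_cylinder(feats, L = 15)
  expect_equal(cyl$R_i, 10)
  expect_equal(pi * (cyl$R_o^2 - cyl$R_i^2) * cyl$L, 500, tolerance = 1e-12)
  # RV_V = 0 specialization
  feats0 <- c(LV_V = 100, RV_V = 0, Epi_V = 400)
  cyl0 <- equivalent_cylinder(feats0, L = 12)
  expect_equal(cyl0$R_o^2 - cyl0$R_i^2, 300 / (pi * 12), tolerance = 1e-12)
  # from a full geometry: preservation to 1e-9 relative
  geom <- resize(fixture_parent(), 1.2, 0.8)
  f <- geometric_features(geom)
  cyl2 <- equivalent_cylinder(geom)
  expect_equal(pi * cyl2$R_i^2 * cyl2$L, f[["LV_V"]], tolerance = 1e-9)
  expect_equal(pi * (cyl2$R_o^2 - cyl2$R_i^2) * cyl2$L,
               f[["Epi_V"]] - f[["LV_V"]] - f[["RV_V"]], tolerance = 1e-9)
  # R_i grows with f_LV
  r_i <- sapply(c(0.8, 1.0, 1.2, 1.4), function(fl)
    equivalent_cylinder(resize(fixture_parent(), fl, 1))$R_i)
  expect_true(all(diff(r_i) > 0))
  expect_error(equivalent_cylinder(c(LV_V = 300, RV_V = 200, Epi_V = 400),
                                   L = 10), "wall")
})

test_that("parent library round-trips through delimited text", {
  parents <- make_parent_library(5, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_parents(parents, f)
  back <- read_parents(f)
  expect_equal(length(back), 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$R_epi, parents[[i]]$R_epi)
    expect_equal(back[[i]]$rv_thickness_frac, parents[[i]]$rv_thickness_frac)
  }
})
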