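# Idealized biventricular anatomy. The LV endocardium and the epicardium
# are truncated semi-ellipsoids of revolution sharing the base plane z = 0
# (apex pointing toward +z); the RV cavity is a crescent: an angular sector
# of the band between an LV-concentric mid-wall surface and the epicardium.
# This parameterized family stands in for an MRI-derived parent-heart
# library and is reduced to an equivalent thick-walled cylinder for the
# inflation mechanics.

#' Default parent-geometry sampling ranges
#'
#' Rat-scale ranges (mm, radians). The LV cavity band is deliberately
#' narrow so that, combined with the LV resize factor sweep (0.7..1.6,
#' which scales cavity volume by its square), the unloaded LV volume spans
#' roughly 35 ul up to about five times that across the library.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
parent_ranges <- function() {
  list(R_epi = c(3.9, 4.3), Z_epi = c(10.5, 11.5),
       R_lv = c(1.99, 2.04), Z_lv = c(8.5, 8.9),
       rv_sector = c(1.2, 2.2), rv_thickness_frac = c(0.30, 0.50))
}

#' Generate one idealized parent geometry
#'
#' Seeded uniform draw from the supplied ranges.
#'
#' @param seed Integer seed (reproducible draw).
#' @param ranges Named list of `c(min, max)` per field; see [parent_ranges()].
#' @param parent_id Identifier stored with the geometry.
#' @return An object of class `parent_geometry`.
#' @export
make_parent <- function(seed, ranges = parent_ranges(), parent_id = seed) {
  for (nm in names(ranges))
    if (ranges[[nm]][1] > ranges[[nm]][2])
      stop(sprintf("inverted range for %s", nm))
  vals <- with_seed(seed, {
    sapply(ranges, function(r) stats::runif(1, r[1], r[2]))
  })
  p <- as.list(vals)
  p$parent_id <- parent_id
  stopifnot(p$R_lv < p$R_epi, p$Z_lv < p$Z_epi,
            p$rv_sector > 0, p$rv_sector < pi,
            p$rv_thickness_frac > 0, p$rv_thickness_frac < 1)
  structure(p, class = "parent_geometry")
}

#' Generate a parent-geometry library
#'
#' @param n Number of parents (default 25).
#' @param seed Integer seed; parent i is drawn with seed `seed + i`.
#' @param ranges See [make_parent()].
#' @return List of `parent_geometry` objects.
#' @export
make_parent_library <- function(n = 25, seed = 1, ranges = parent_ranges()) {
  lapply(seq_len(n), function(i)
    make_parent(seed + i, ranges = ranges, parent_id = i))
}

#' Resize the ventricular chambers of a parent geometry
#'
#' The LV endocardial surface is scaled isotropically in the short-axis
#' (X-Y) plane by `f_LV` (the long-axis apex depth is unchanged) and the RV
#' cavity thickness by `f_RV`; the epicardial surface is kept fixed.
#'
#' @param parent A `parent_geometry`.
#' @param f_LV,f_RV Resize factors in [0.7, 1.6].
#' @return An object of class `heart_geometry`.
#' @export
resize <- function(parent, f_LV = 1, f_RV = 1) {
  if (f_LV < 0.7 || f_LV > 1.6 || f_RV < 0.7 || f_RV > 1.6)
    stop("resize factors must lie within [0.7, 1.6]")
  if (f_LV * parent$R_lv >= parent$R_epi)
    stop("resized LV endocardium would intersect the epicardium")
  if (f_RV * parent$rv_thickness_frac >= 1)
    stop("resized RV cavity would exit the epicardium")
  structure(list(parent = parent, f_LV = f_LV, f_RV = f_RV),
            class = "heart_geometry")
}

# ellipsoid-of-revolution profile radius at depth z (semi-axes R, Z)
.ell_r <- function(z, R, Z) R * sqrt(pmax(0, 1 - (z / Z)^2))

# lateral surface area of a sector (frac of 2*pi) of the surface of
# revolution r(z) over [0, z1], by quadrature; the substitution
# z = z1 sin(t) removes the apex 1/sqrt singularity of the ellipse profile
.rev_area <- function(rfun, drfun, z1, frac = 1, rel.tol = 1e-10) {
  f <- function(t) {
    z <- z1 * sin(t)
    g <- 2 * pi * frac * rfun(z) * sqrt(1 + drfun(z)^2)
    g * z1 * cos(t)
  }
  stats::integrate(f, 0, pi / 2, rel.tol = rel.tol, subdivisions = 400L)$value
}

# d r / d z for the ellipse profile (singular at z = Z; integrable)
.ell_dr <- function(z, R, Z) {
  s <- sqrt(pmax(1e-300, 1 - (z / Z)^2))
  -R * z / (Z^2 * s)
}

# RV crescent surfaces of a geometry: inner = LV-concentric mid-wall
# (parent LV used, so the RV is unaffected by f_LV), outer = inner plus
# f_RV-scaled fraction of the gap to the epicardium; angular extent
# rv_sector; spans the base plane down to the parent LV apex depth.
.rv_surfaces <- function(geom) {
  p <- geom$parent
  r_in <- function(z) (.ell_r(z, p$R_lv, p$Z_lv) + .ell_r(z, p$R_epi, p$Z_epi)) / 2
  w <- geom$f_RV * p$rv_thickness_frac
  r_out <- function(z) r_in(z) + w * (.ell_r(z, p$R_epi, p$Z_epi) - r_in(z))
  list(r_in = r_in, r_out = r_out, z1 = p$Z_lv, phi = p$rv_sector)
}

#' Extract the 12 geometric features of a heart geometry
#'
#' Features (canonical order): LV cavity volume `LV_V` (ul) and endocardial
#' area `LV_A` (mm^2); RV cavity volume `RV_V` and endocardial area `RV_A`;
#' the epicardium-enclosed cross-section areas `S_A1`..`S_A6` of six
#' equally spaced short-axis slices from the base plane (`S_A1`) toward the
#' apex (`S_A6` at 5/6 of the apex distance); epicardial interior volume
#' `Epi_V` and surface area `Epi_A`. Ellipsoidal volumes are closed-form;
#' areas and the RV crescent use numerical quadrature.
#'
#' @param geom A `heart_geometry` (or a `parent_geometry`, taken at
#'   f_LV = f_RV = 1).
#' @return Named numeric vector of length 12.
#' @export
geometric_features <- function(geom) {
  if (inherits(geom, "parent_geometry")) geom <- resize(geom, 1, 1)
  p <- geom$parent
  R_lv <- geom$f_LV * p$R_lv
  LV_V <- 2 / 3 * pi * R_lv^2 * p$Z_lv
  LV_A <- .rev_area(function(z) .ell_r(z, R_lv, p$Z_lv),
                    function(z) .ell_dr(z, R_lv, p$Z_lv), p$Z_lv)
  Epi_V <- 2 / 3 * pi * p$R_epi^2 * p$Z_epi
  Epi_A <- .rev_area(function(z) .ell_r(z, p$R_epi, p$Z_epi),
                     function(z) .ell_dr(z, p$R_epi, p$Z_epi), p$Z_epi)
  z_k <- (0:5) / 6 * p$Z_epi
  S_A <- pi * .ell_r(z_k, p$R_epi, p$Z_epi)^2
  rv <- .rv_surfaces(geom)
  RV_V <- stats::integrate(function(z) rv$phi / 2 * (rv$r_out(z)^2 - rv$r_in(z)^2),
                           0, rv$z1, rel.tol = 1e-8, subdivisions = 400L)$value
  # endocardial area of the crescent: the two bounding sector surfaces
  eps <- 1e-9
  dnum <- function(f) function(z) {
    zl <- pmax(0, z - eps); zr <- pmin(rv$z1, z + eps)
    (f(zr) - f(zl)) / (zr - zl)
  }
  RV_A <- .rev_area(rv$r_in, dnum(rv$r_in), rv$z1, frac = rv$phi / (2 * pi),
                    rel.tol = 1e-8) +
          .rev_area(rv$r_out, dnum(rv$r_out), rv$z1, frac = rv$phi / (2 * pi),
                    rel.tol = 1e-8)
  c(LV_V = LV_V, LV_A = LV_A, RV_V = RV_V, RV_A = RV_A,
    S_A1 = S_A[1], S_A2 = S_A[2], S_A3 = S_A[3], S_A4 = S_A[4],
    S_A5 = S_A[5], S_A6 = S_A[6], Epi_V = Epi_V, Epi_A = Epi_A)
}

#' Rule-based transmural fiber architecture
#'
#' The helix angle turns linearly with transmural depth from a positive
#' value at the endocardium to a negative value at the epicardium. The wall
#' is divided into `n_layers` layers of equal thickness; each layer carries
#' the angle at its midpoint depth.
#'
#' @param theta_endo Endocardial helix angle, in (0, pi/2) radians.
#' @param theta_epi Epicardial helix angle, in (-pi/2, 0) radians.
#' @param n_layers Number of layers (default 4).
#' @return An object of class `fiber_architecture` with `layer_angles`.
#' @export
fiber_layers <- function(theta_endo, theta_epi, n_layers = 4) {
  if (!(theta_endo > 0 && theta_endo < pi / 2))
    stop("theta_endo must lie in (0, pi/2)")
  if (!(theta_epi > -pi / 2 && theta_epi < 0))
    stop("theta_epi must lie in (-pi/2, 0)")
  d_m <- (seq_len(n_layers) - 0.5) / n_layers
  structure(list(theta_endo = theta_endo, theta_epi = theta_epi,
                 n_layers = n_layers,
                 layer_angles = theta_endo + (theta_epi - theta_endo) * d_m),
            class = "fiber_architecture")
}

#' Reduce a heart geometry to an equivalent thick-walled cylinder
#'
#' Length equals the epicardial base-to-apex length; the inner radius
#' preserves the LV cavity (lumen) volume and the outer radius preserves
#' the LV wall volume Epi_V - LV_V - RV_V.
#'
#' @param geom A `heart_geometry`, or a named feature vector from
#'   [geometric_features()] together with `L`.
#' @param L Cylinder length (mm); required when `geom` is a feature vector.
#' @return An object of class `cylinder_model` with `R_i`, `R_o`, `L`.
#' @export
equivalent_cylinder <- function(geom, L = NULL) {
  if (inherits(geom, "heart_geometry")) {
    feats <- geometric_features(geom)
    L <- geom$parent$Z_epi
  } else feats <- geom
  if (is.null(L)) stop("cylinder length L required")
  wall_V <- feats[["Epi_V"]] - feats[["LV_V"]] - feats[["RV_V"]]
  if (wall_V <= 0) stop("non-positive LV wall volume")
  R_i <- sqrt(feats[["LV_V"]] / (pi * L))
  R_o <- sqrt(R_i^2 + wall_V / (pi * L))
  structure(list(R_i = R_i, R_o = R_o, L = L), class = "cylinder_model")
}

#' Write / read a parent library as delimited text
#'
#' One record per parent with named fields.
#' @param parents List of `parent_geometry` objects.
#' @param file Path.
#' @export
write_parents <- function(parents, file) {
  d <- do.call(rbind, lapply(parents, function(p)
    data.frame(parent_id = p$parent_id, R_epi = p$R_epi, Z_epi = p$Z_epi,
               R_lv = p$R_lv, Z_lv = p$Z_lv, rv_sector = p$rv_sector,
               rv_thickness_frac = p$rv_thickness_frac)))
  utils::write.csv(format(d, digits = 17, trim = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_parents
#' @export
read_parents <- function(file) {
  d <- utils::read.csv(file)
  lapply(seq_len(nrow(d)), function(i) {
    p <- as.list(d[i, c("R_epi", "Z_epi", "R_lv", "Z_lv",
                        "rv_sector", "rv_thickness_frac")])
    p$parent_id <- d$parent_id[i]
    structure(p, class = "parent_geometry")
  })
}
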