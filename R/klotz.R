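# Universal (Klotz-style) EDPVR: volume normalization removes most of the
# geometric variation between hearts, so a single power law
# P = An * Vn^Bn fitted to the pooled normalized training curves lets a
# full EDPVR be reconstructed from one measured (P_ED, V_ED) point.

#' Klotz volume normalization of an EDPVR
#'
#' Vn(p) = (V(p) - V0) / (V30 - V0), where V30 is the volume at the 30 mmHg
#' end of the grid; Vn(30) = 1 and Vn -> 0 at zero load.
#'
#' @param curve An [edpvr()] object.
#' @return Numeric vector of normalized volumes on the curve's grid.
#' @export
normalize_curve <- function(curve) {
  if (any(diff(curve$volumes) <= 0)) stop("non-monotone EDPVR")
  V30 <- curve$volumes[length(curve$volumes)]
  if (V30 <= curve$V0) stop("V30 must exceed V0")
  (curve$volumes - curve$V0) / (V30 - curve$V0)
}

#' Fit the universal EDPVR power law to a family of curves
#'
#' Pools all points of the normalized curves with Vn above a floor and
#' fits P = An * Vn^Bn by linear regression of log P on log Vn.
#'
#' @param curves List of [edpvr()] objects (one or more; a single curve is
#'   accepted and duplicates leave the fit unchanged).
#' @param vn_floor Normalized-volume floor excluded from the log-log fit
#'   (default 0.01).
#' @return An object of class `universal_curve` with `An` (mmHg), `Bn`
#'   (dimensionless) and `fit_r2`.
#' @export
fit_universal <- function(curves, vn_floor = 0.01) {
  if (length(curves) < 1) stop("at least one curve required")
  vn <- unlist(lapply(curves, normalize_curve))
  p <- unlist(lapply(curves, function(cv) cv$pressures))
  keep <- vn > vn_floor
  if (sum(keep) < 3 || stats::sd(log(vn[keep])) == 0)
    stop("degenerate pooled data for universal fit")
  fit <- stats::lm(log(p[keep]) ~ log(vn[keep]))
  structure(list(An = exp(unname(stats::coef(fit)[1])),
                 Bn = unname(stats::coef(fit)[2]),
                 fit_r2 = summary(fit)$r.squared,
                 vn_floor = vn_floor),
            class = "universal_curve")
}

#' @export
print.universal_curve <- function(x, ...) {
  cat(sprintf("universal EDPVR: P = %.4g * Vn^%.4g (mmHg), fit R^2 = %.4f\n",
              x$An, x$Bn, x$fit_r2))
  invisible(x)
}

#' Reconstruct a full EDPVR from a single (P_ED, V_ED) point
#'
#' The unloaded volume is estimated by the empirical relation
#' V0 = V_ED (k0 - k1 P_ED) (defaults k0 = 0.6, k1 = 0.006 per mmHg), the
#' 30 mmHg volume from the universal curve,
#' V30 = V0 + (V_ED - V0) / (P_ED/An)^(1/Bn), and the curve itself as the
#' power law P = alpha V^beta through (P_ED, V_ED) and (30, V30), sampled
#' by inversion on the standard pressure grid.
#'
#' @param P_ED End-diastolic pressure (mmHg), 0 < P_ED <= 30.
#' @param V_ED End-diastolic volume (ul).
#' @param uc A `universal_curve` from [fit_universal()].
#' @param grid Pressure grid in mmHg (default [pressure_grid()]).
#' @param k0,k1 Constants of the unloaded-volume relation.
#' @return An [edpvr()] object passing exactly through (P_ED, V_ED).
#' @export
edpvr_from_point <- function(P_ED, V_ED, uc, grid = pressure_grid(),
                             k0 = 0.6, k1 = 0.006) {
  if (P_ED <= 0 || P_ED > 30) stop("P_ED must lie in (0, 30] mmHg")
  V0 <- V_ED * (k0 - k1 * P_ED)
  if (V_ED <= V0) stop("V_ED does not exceed the estimated unloaded volume")
  if (abs(P_ED - 30) < 1e-9) {
    # endpoint case (degenerate beta): anchor the universal exponent at
    # (30, V_ED)
    V30 <- V_ED
    beta <- uc$Bn
  } else {
    V30 <- V0 + (V_ED - V0) / (P_ED / uc$An)^(1 / uc$Bn)
    beta <- log(P_ED / 30) / log(V_ED / V30)
  }
  # single-beat power law P = alpha V^beta with alpha = 30 / V30^beta,
  # sampled by inversion on the pressure grid; its low-pressure limb falls
  # below the V0 estimate, which is therefore kept as metadata (`V0_est`)
  # while the container's V0 is capped below the first grid volume.
  vols <- V30 * (grid / 30)^(1 / beta)
  out <- edpvr(grid, vols, V0 = min(V0, vols[1] * (1 - 1e-9)))
  out$V0_est <- V0
  out
}
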