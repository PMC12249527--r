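# Low-Reynolds Stokes drag of a tri-axial ellipsoid swimming along its major
# axis, and the constant-thrust velocity prediction.
#
#   F = 6 pi eta v sqrt(b c) K(beta),  beta = a / sqrt(b c)
#
# The equivalent radius is the geometric mean sqrt(b*c) of the two transverse
# semi-axes (the dimensionally consistent reading, which also reduces to
# classical Stokes drag 6 pi eta r v for a sphere), and K is the prolate
# shape-factor correction, K(1) = 1. With the flagellar thrust approximately
# constant, drag balance gives v(t) = v0 * eta0 / eta(t): morphology cancels,
# and any shortfall of the measured velocity below this prediction is a
# physiological (osmotic-stress) deficit, not viscosity.

#' Ellipsoid axis ratio beta
#'
#' Ratio of the major semi-axis to the geometric mean of the two transverse
#' semi-axes, `beta = a / sqrt(b c)`; 1 for a sphere, ~2.04 for the default
#' sperm-head axes.
#'
#' @param morph A [sperm_morphology()] object.
#' @return Dimensionless ratio >= 1.
#' @examples
#' axis_ratio(sperm_morphology(2.5, 1.0, 1.5))  # ~2.04
#' @export
axis_ratio <- function(morph = sperm_morphology()) {
  assert_morphology(morph)
  morph$a / sqrt(morph$b * morph$c)
}

#' Prolate-ellipsoid Stokes shape factor K
#'
#' Drag correction for a prolate ellipsoid translating along its major axis:
#' `K = (4/3)(beta^2 - 1) / [((2 beta^2 - 1)/sqrt(beta^2 - 1)) *
#' ln(beta + sqrt(beta^2 - 1)) - beta]`, with `K(1) = 1` (the sphere limit,
#' by analytic continuation). Strictly increasing in `beta`; ~1.22 at
#' `beta = 2.08`. Oblate shapes (`beta < 1`) are rejected.
#'
#' @param beta Axis ratio, >= 1. Vectorized.
#' @return Dimensionless factor >= 1.
#' @examples
#' shape_factor(2.08)  # ~1.22
#' shape_factor(1)     # 1
#' @export
shape_factor <- function(beta) {
  if (any(!is.finite(beta)) || any(beta < 1))
    stop("`beta` must be >= 1 (oblate ellipsoids are out of scope)",
         call. = FALSE)
  k_one <- function(b) {
    if (b == 1) return(1)
    e <- sqrt(b^2 - 1)
    (4 / 3) * (b^2 - 1) / (((2 * b^2 - 1) / e) * log(b + e) - b)
  }
  vapply(beta, k_one, numeric(1))
}

#' Stokes drag force on a swimming ellipsoidal cell
#'
#' `F = 6 pi eta v sqrt(b c) K(beta)` converted to newtons; linear in both
#' viscosity and speed, and equal to classical Stokes drag `6 pi eta r v`
#' for a sphere.
#'
#' @param eta Viscosity, cP (> 0).
#' @param v Swimming speed, um/s (>= 0).
#' @param morph A [sperm_morphology()] object.
#' @return Drag force in newtons.
#' @examples
#' drag_force(1.876, 66)  # ~1e-12 N scale
#' @export
drag_force <- function(eta, v, morph = sperm_morphology()) {
  assert_morphology(morph)
  if (any(!is.finite(eta)) || any(eta <= 0))
    stop("`eta` must be positive", call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0))
    stop("`v` must be nonnegative", call. = FALSE)
  r_m <- sqrt(morph$b * morph$c) * 1e-6
  6 * pi * (eta * CP_TO_PA_S) * (v * 1e-6) * r_m * shape_factor(axis_ratio(morph))
}

#' Constant-thrust velocity prediction under changed viscosity
#'
#' With the flagellar driving force constant, drag balance implies
#' `v = v0 * eta0 / eta_t`; the morphology factor cancels. This is the
#' velocity a cell would have if viscosity were the only thing slowing it.
#'
#' @param v0 Reference speed, um/s (> 0).
#' @param eta0 Viscosity at which `v0` was measured, cP (> 0).
#' @param eta_t Current viscosity, cP (> 0). Vectorized.
#' @return Predicted speed, um/s.
#' @examples
#' predict_velocity(66, 1.876, 2.862)  # ~43.3 um/s
#' @export
predict_velocity <- function(v0, eta0, eta_t) {
  if (any(!is.finite(c(v0, eta0))) || v0 <= 0 || eta0 <= 0)
    stop("`v0` and `eta0` must be positive", call. = FALSE)
  if (any(!is.finite(eta_t)) || any(eta_t <= 0))
    stop("`eta_t` must be positive", call. = FALSE)
  v0 * eta0 / eta_t
}

#' Physiological velocity deficit
#'
#' Ratio of the measured to the viscosity-predicted speed. A value of 1
#' means viscosity fully explains the slowdown; values below 1 quantify the
#' physiological (osmotic-stress) component that viscosity cannot account
#' for.
#'
#' @param v_measured Measured speed, um/s (>= 0). Vectorized.
#' @param v_predicted Constant-thrust prediction, um/s (> 0).
#' @return Dimensionless ratio >= 0.
#' @examples
#' physiological_deficit(40, 43.3)  # ~0.92
#' @export
physiological_deficit <- function(v_measured, v_predicted) {
  if (any(!is.finite(v_predicted)) || any(v_predicted <= 0))
    stop("`v_predicted` must be positive", call. = FALSE)
  if (any(!is.finite(v_measured)) || any(v_measured < 0))
    stop("`v_measured` must be nonnegative", call. = FALSE)
  v_measured / v_predicted
}
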