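# Two independent micro-viscometry routes for droplets, plus the macroscopic
# rheometer fit.
#
# Route 1 (fluorescence polarization): the Perrin equation
#   1/p - 1/3 = (1/p0 - 1/3) (1 + tau/tau_r),   tau_r = eta V_mol / (R_gas T)
# links the measured polarization p of a dye to the solution viscosity.
# Inverted for eta:
#   eta = tau R_gas T (rho/M_W) (1/p0 - 1/3) / (1/p - 1/p0)
# (the unique arrangement consistent with the Perrin relation above; verified
# by the forward/inverse roundtrip test).
#
# Route 2 (volume ratio): for ionic solutions eta_s/eta_w = 1 + Lambda*C, and
# since C scales with V0/Vt as water leaves, eta_t = eta_w (1 + lambdaC0 *
# V0/Vt) with lambdaC0 = eta_s0/eta_w - 1 ~ 1.108 identified from the two
# measured viscosities (Lambda and C0 are not separately identifiable).
# No instrument G-factor correction is applied: intensities are taken as
# already corrected.

#' Fluorescence polarization from an intensity pair
#'
#' `p = (I_par - I_perp) / (I_par + I_perp)` from emission intensities
#' measured through analyzers parallel and perpendicular to the excitation
#' polarization.
#'
#' @param I_par,I_perp Nonnegative emission intensities (arbitrary units,
#'   same scale); their sum must be positive. Vectorized.
#' @return Polarization in `[-1, 1]`.
#' @examples
#' polarization(55, 45)  # 0.1
#' @export
polarization <- function(I_par, I_perp) {
  if (any(!is.finite(I_par)) || any(!is.finite(I_perp)) ||
      any(I_par < 0) || any(I_perp < 0))
    stop("intensities must be finite and nonnegative", call. = FALSE)
  tot <- I_par + I_perp
  if (any(tot <= 0))
    stop("total intensity must be positive", call. = FALSE)
  (I_par - I_perp) / tot
}

#' Viscosity from fluorescence polarization (Perrin equation)
#'
#' Inverts the Perrin relation for the solution viscosity given a measured
#' polarization. Valid for `0 < p < p0`; as `p` approaches the intrinsic
#' polarization `p0` rotation ceases and the implied viscosity diverges.
#'
#' @param p Measured polarization, in `(0, p0)`. Vectorized.
#' @param spec A [fluorophore_spec()] object.
#' @return Viscosity in cP.
#' @examples
#' sp <- fluorophore_spec()
#' perrin_viscosity(polarization_from_viscosity(1.876, sp), sp)  # 1.876
#' @export
perrin_viscosity <- function(p, spec = fluorophore_spec()) {
  assert_fluorophore(spec)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("`p` must be positive (fast-rotation limit p -> 0 excluded)",
         call. = FALSE)
  if (any(p >= spec$p0))
    stop("`p` must be below the intrinsic polarization p0 ",
         "(p >= p0 would imply infinite viscosity)", call. = FALSE)
  tau_s <- spec$tau_ns * 1e-9
  rho_over_MW <- (spec$density * 1000) / (spec$M_W / 1000)  # mol/m^3
  eta_pa_s <- tau_s * R_GAS * spec$T_K * rho_over_MW *
    (1 / spec$p0 - 1 / 3) / (1 / p - 1 / spec$p0)
  eta_pa_s / CP_TO_PA_S
}

#' Polarization expected at a given viscosity (forward Perrin model)
#'
#' The forward model used by the synthetic-data generator: rotational
#' correlation time `tau_r = eta V_mol / (R_gas T)`, then
#' `1/p = 1/3 + (1/p0 - 1/3)(1 + tau/tau_r)`. Monotone increasing in `eta`,
#' approaching `p0` as the solution freezes and 0 in the fast-rotation limit.
#'
#' @param eta Viscosity in cP (> 0). Vectorized.
#' @param spec A [fluorophore_spec()] object.
#' @return Polarization in `(0, p0)`.
#' @examples
#' polarization_from_viscosity(1.876)  # ~0.041 for fluorescein
#' @export
polarization_from_viscosity <- function(eta, spec = fluorophore_spec()) {
  assert_fluorophore(spec)
  if (any(!is.finite(eta)) || any(eta <= 0))
    stop("`eta` must be positive", call. = FALSE)
  eta_pa_s <- eta * CP_TO_PA_S
  V_mol <- (spec$M_W / 1000) / (spec$density * 1000)        # m^3/mol
  tau_r <- eta_pa_s * V_mol / (R_GAS * spec$T_K)            # s
  inv_p <- 1 / 3 + (1 / spec$p0 - 1 / 3) * (1 + spec$tau_ns * 1e-9 / tau_r)
  1 / inv_p
}

#' Suspension viscosity from the droplet volume ratio
#'
#' The bright-field route: as water leaves, the solute concentration (and
#' with it the viscosity excess over water) grows with the volume ratio:
#' `eta_t = eta_w (1 + lambda_c0 * V0 / Vt)`. At `Vt = V0` and the default
#' constants this returns the measured initial suspension viscosity
#' 1.876 cP.
#'
#' @param V0 Initial droplet volume (any consistent unit).
#' @param Vt Current droplet volume, `0 < Vt <= V0` (droplets cannot grow
#'   under diffusion loss). Vectorized.
#' @param props A [medium_properties()] object (supplies `eta_w`).
#' @param lambda_c0 The dimensionless solute-viscosity product; defaults to
#'   [lambda_c0()] of the medium's two viscosities (~1.108).
#' @return Viscosity in cP.
#' @examples
#' viscosity_from_volume_ratio(1, 1)    # 1.876 cP
#' viscosity_from_volume_ratio(2, 1)    # 2.862 cP
#' @export
viscosity_from_volume_ratio <- function(V0, Vt, props = medium_properties(),
                                        lambda_c0 = NULL) {
  assert_medium(props)
  if (is.null(lambda_c0))
    lambda_c0 <- props$eta_s0 / props$eta_w - 1
  assert_positive(V0, "V0"); assert_positive(Vt, "Vt")
  if (any(Vt > V0 * (1 + 1e-12)))
    stop("`Vt` cannot exceed `V0`: droplets cannot grow under diffusion loss",
         call. = FALSE)
  if (lambda_c0 < 0) stop("`lambda_c0` must be nonnegative", call. = FALSE)
  props$eta_w * (1 + lambda_c0 * V0 / Vt)
}

#' Solute-viscosity product from the two measured viscosities
#'
#' Identifies the product `Lambda * C0` of the linear ionic-viscosity law
#' `eta_s/eta_w = 1 + Lambda C` from the initial suspension viscosity and the
#' viscosity of water: `lambda_c0 = eta_s0/eta_w - 1` (~1.108 for the
#' defaults). `Lambda` and `C0` are not separately identifiable.
#'
#' @param eta_s0 Initial suspension viscosity, cP.
#' @param eta_w Water viscosity, cP, with `eta_s0 >= eta_w > 0`.
#' @return A nonnegative dimensionless scalar.
#' @examples
#' lambda_c0(1.876, 0.89)  # ~1.108
#' @export
lambda_c0 <- function(eta_s0 = 1.876, eta_w = 0.89) {
  assert_positive(eta_w, "eta_w")
  if (eta_s0 < eta_w)
    stop("`eta_s0` must be >= `eta_w`", call. = FALSE)
  eta_s0 / eta_w - 1
}

#' Two-point Bingham-plastic fit from rheometer readings
#'
#' A rotational rheometer run at two speeds gives two points on the flow
#' curve, enough to define the Bingham model `tau = tau_y + mu_p * gamma`.
#' Returns the yield stress (intercept) and plastic viscosity (slope); a
#' negative intercept is flagged as non-physical (the fluid is then better
#' described as Newtonian over the probed range).
#'
#' @param gamma1,gamma2 Shear rates, 1/s (positive, distinct).
#' @param tau1,tau2 Shear stresses, Pa.
#' @return A list with `yield_stress_pa`, `plastic_viscosity_cp` and
#'   `physical` (`FALSE` when the intercept is negative).
#' @examples
#' bingham_two_point(100, 0.3, 200, 0.4)  # tau_y 0.2 Pa, mu_p 1 cP
#' @export
bingham_two_point <- function(gamma1, tau1, gamma2, tau2) {
  stopifnot(is.finite(gamma1), is.finite(gamma2),
            is.finite(tau1), is.finite(tau2))
  if (gamma1 <= 0 || gamma2 <= 0)
    stop("shear rates must be positive", call. = FALSE)
  if (gamma1 == gamma2)
    stop("degenerate fit: the two shear rates must differ", call. = FALSE)
  mu_pa_s <- (tau2 - tau1) / (gamma2 - gamma1)
  tau_y <- tau1 - mu_pa_s * gamma1
  list(yield_stress_pa = tau_y,
       plastic_viscosity_cp = mu_pa_s / CP_TO_PA_S,
       physical = tau_y >= -sqrt(.Machine$double.eps))
}
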