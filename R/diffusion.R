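# Water-loss kinetics of a droplet under oil.
#
# Fick's first law across the curved cap surface, combined with the cap
# geometry, makes the surface area shrink at a constant rate:
#
#   j  = sqrt(c_S) * (1 - sigma) * D*C0 / sqrt(S)          (mass flux)
#   dS/dt = -[sqrt(c_S) / ((3/2) c_VS)] * (1 - sigma) * D*C0 / rho_w
#
# The bracketed flux-balance factor evaluates to ~9.56 at 51 deg (the
# quotient of the two geometric constants ~1.526 and ~0.160 carried at full
# precision), giving ~ -108 um^2/min with the default D*C0. Because the rate
# is constant, S(t) is exactly linear and the whole droplet state over time
# is closed-form; no ODE solver is involved and `dt` only controls output
# sampling. Far-field boundary conditions C_inf ~ 0 and S_inf >> S are baked
# into the closed forms. Saturated oil (sigma = 1) nulls the interfacial
# gradient and freezes every dynamic quantity.

#' Flux-balance factor of the constant surface-shrinkage law
#'
#' The dimensionless geometric factor relating the surface shrink rate to
#' `D*C0 / rho_w`: `dS/dt = -factor * (1 - sigma) * D*C0 / rho_w`. Equals
#' `sqrt(c_S) / ((3/2) c_VS)`, about 9.56 at a 51-degree contact angle.
#'
#' @param geom A [cap_geometry()] object.
#' @return A positive scalar.
#' @examples
#' flux_balance_factor(cap_geometry(51))  # ~9.56
#' @export
flux_balance_factor <- function(geom = cap_geometry(51)) {
  assert_geometry(geom)
  sqrt(geom$c_S) / (1.5 * geom$c_VS)
}

#' Constant surface-area shrink rate of a droplet under oil
#'
#' Rate of change of the curved surface area, in um^2/min. Negative for
#' fresh oil; exactly zero for water-saturated oil (`saturation = 1`) or a
#' vanishing `DC0`. Independent of droplet size. With default properties and
#' a 51-degree cap the rate is about -108 um^2/min.
#'
#' @param props A [medium_properties()] object.
#' @param geom A [cap_geometry()] object.
#' @return Rate in um^2/min (<= 0).
#' @examples
#' surface_shrink_rate(medium_properties())  # ~ -108 um^2/min
#' @export
surface_shrink_rate <- function(props, geom = cap_geometry(51)) {
  assert_medium(props); assert_geometry(geom)
  rate_m2_s <- -flux_balance_factor(geom) * (1 - props$saturation) *
    props$DC0 / props$rho_w
  rate_m2_s * M2_PER_S_TO_UM2_PER_MIN
}

#' Surface shrink rate from a measured footprint-area rate
#'
#' The bright-field measurement route: the microscope measures the footprint
#' area A, and `dS/dt = c_SA * dA/dt`. With the measured
#' `dA/dt = -88.4 um^2/min` at 51 degrees this gives about -108.5 um^2/min,
#' in close agreement with the diffusion route of [surface_shrink_rate()].
#'
#' @param dAdt Measured footprint-area rate, um^2/min (negative when
#'   shrinking).
#' @param geom A [cap_geometry()] object.
#' @return Rate in um^2/min.
#' @examples
#' shrink_rate_from_dAdt(-88.4, cap_geometry(51))  # ~ -108.5
#' @export
shrink_rate_from_dAdt <- function(dAdt, geom = cap_geometry(51)) {
  assert_geometry(geom)
  stopifnot(is.numeric(dAdt), is.finite(dAdt))
  geom$c_SA * dAdt
}

#' Interfacial water mass flux out of the droplet
#'
#' Mass flux density through the curved surface,
#' `j = sqrt(c_S) * (1 - sigma) * D*C0 / sqrt(S)` in kg/(m^2 s); it scales
#' as `S^(-1/2)`, which is why small droplets lose a larger fraction of
#' their water. The total molecular current is `I = j * S / M_water`
#' (mol/s), available via `total = TRUE` as mass current `j * S` in kg/s.
#'
#' @param S Curved surface area, um^2 (> 0).
#' @param props A [medium_properties()] object.
#' @param geom A [cap_geometry()] object.
#' @param total If `TRUE`, return the total mass current `j * S` in kg/s
#'   instead of the flux density.
#' @return Flux in kg/(m^2 s), or kg/s when `total = TRUE`.
#' @examples
#' boundary_flux(1e4, medium_properties())  # ~2.87e-6 kg/(m^2 s)
#' @export
boundary_flux <- function(S, props, geom = cap_geometry(51), total = FALSE) {
  assert_medium(props); assert_geometry(geom); assert_positive(S, "S")
  S_m2 <- S * 1e-12
  j <- sqrt(geom$c_S) * (1 - props$saturation) * props$DC0 / sqrt(S_m2)
  if (total) j * S_m2 else j
}

#' Solute amount in a droplet of given initial volume
#'
#' `n0 = osmolarity * V0`, the (conserved) number of osmoles in the droplet.
#'
#' @param V0_nl Initial volume, nL.
#' @param props A [medium_properties()] object.
#' @return Solute amount in mol.
#' @examples
#' solute_amount(1, medium_properties())  # 1.5e-10 mol
#' @export
solute_amount <- function(V0_nl, props) {
  assert_medium(props); assert_positive(V0_nl, "V0_nl")
  props$osmolarity * V0_nl * 1e-9   # Osm/L * L
}

#' Closed-form droplet state over time
#'
#' Simulates the shrinkage of a droplet under oil: the surface area falls
#' linearly at the constant rate of [surface_shrink_rate()], the volume
#' follows `V = c_VS S^(3/2)`, the solute concentration `C = n0 / V` rises,
#' and the suspension viscosity grows with the volume ratio
#' `eta = eta_w (1 + lambda_C0 V0 / V)`. If the droplet would vanish within
#' `duration` the trajectory is truncated there and `vanished_at` records the
#' vanishing time `S0 / |dS/dt|`.
#'
#' @param V0_nl Initial volume, nL (> 0).
#' @param duration Simulated time span, min (> 0).
#' @param dt Output sampling interval, min (> 0); the solution is exact, so
#'   `dt` has no accuracy role.
#' @param geom A [cap_geometry()] object.
#' @param props A [medium_properties()] object.
#' @param n0 Solute amount in mol; defaults to `osmolarity * V0` via
#'   [solute_amount()].
#' @return A `droplet_trajectory`: a data frame with columns `time_min`,
#'   `S_um2`, `V_um3`, `V_nL`, `C_mol_m3`, `eta_cP`, with attributes `n0`
#'   (mol) and `vanished_at` (min, or `NA` if the droplet outlives
#'   `duration`).
#' @examples
#' tr <- simulate_shrinkage(0.1, duration = 30, dt = 1)
#' tail(tr, 2)
#' @export
simulate_shrinkage <- function(V0_nl, duration = 30, dt = 1,
                               geom = cap_geometry(51),
                               props = medium_properties(),
                               n0 = NULL) {
  assert_geometry(geom); assert_medium(props)
  assert_positive(V0_nl, "V0_nl")
  assert_positive(duration, "duration"); assert_positive(dt, "dt")
  if (is.null(n0)) n0 <- solute_amount(V0_nl, props)
  assert_positive(n0, "n0")

  V0_um3 <- nl_to_um3(V0_nl)
  S0 <- surface_from_volume(V0_um3, geom)
  rate <- surface_shrink_rate(props, geom)     # um^2/min, <= 0

  vanished_at <- if (rate < 0) S0 / abs(rate) else NA_real_
  times <- seq(0, duration, by = dt)
  if (is.finite(vanished_at) && vanished_at <= duration)
    times <- times[times < vanished_at - sqrt(.Machine$double.eps)]

  S <- S0 + rate * times
  V_um3 <- volume_from_surface(S, geom)
  V_nL <- um3_to_nl(V_um3)
  C <- n0 / (V_um3 * 1e-18)                    # mol/m^3
  lam <- lambda_c0(props$eta_s0, props$eta_w)
  eta <- props$eta_w * (1 + lam * V0_um3 / V_um3)

  out <- data.frame(time_min = times, S_um2 = S, V_um3 = V_um3, V_nL = V_nL,
                    C_mol_m3 = C, eta_cP = eta)
  attr(out, "n0") <- n0
  attr(out, "vanished_at") <-
    if (is.finite(vanished_at) && vanished_at <= duration) vanished_at
    else NA_real_
  class(out) <- c("droplet_trajectory", "data.frame")
  out
}

#' Rate of solute-concentration increase in a shrinking droplet
#'
#' Exact chain rule `dC/dt = (dC/dS)(dS/dt)` for a droplet of current volume
#' `V` holding solute amount `n0`:
#' `dC/dS = -(3/2) n0 / (c_VS S^(5/2))`. Positive whenever the droplet
#' shrinks; at fixed `n0` it scales as `V^(-5/3)`, which produces the sharp
#' concentration "leap" in sub-30-nL droplets. With the default
#' `n0 = osmolarity * V` (each droplet starting at physiological
#' concentration) the initial rate instead scales as `V^(-2/3)`.
#'
#' @param V_nl Current droplet volume, nL (> 0).
#' @param geom A [cap_geometry()] object.
#' @param props A [medium_properties()] object.
#' @param n0 Solute amount in mol; defaults to `osmolarity * V`. Pass a fixed
#'   value (e.g. `1e-9`) to evaluate the fixed-solute `V^(-5/3)` law.
#' @return Rate of concentration change, mol/(m^3 min) (>= 0).
#' @examples
#' concentration_rate(1, n0 = 1e-9) / concentration_rate(2, n0 = 1e-9)
#' # = 2^(5/3)
#' @export
concentration_rate <- function(V_nl, geom = cap_geometry(51),
                               props = medium_properties(), n0 = NULL) {
  assert_geometry(geom); assert_medium(props); assert_positive(V_nl, "V_nl")
  if (is.null(n0)) n0 <- solute_amount(V_nl, props)
  assert_positive(n0, "n0")
  S <- surface_from_volume(nl_to_um3(V_nl), geom)          # um^2
  dCdS <- dCdt_prefactor(n0, geom) * S^(-2.5)              # mol/um^3 per um^2
  dSdt <- surface_shrink_rate(props, geom)                 # um^2/min
  dCdS * dSdt * 1e18                                       # mol/m^3 per min
}

#' Prefactor of the S^(-5/2) term in dC/dS
#'
#' For solute amount `n0`, `dC/dS = prefactor * S^(-5/2)` with C in mol/um^3
#' and S in um^2; the prefactor is `-(3/2) n0 / c_VS`, about `-1.41e-8`
#' mol um^-5 at `n0 = 1e-9` mol and a 51-degree cap.
#'
#' @param n0 Solute amount, mol (> 0).
#' @param geom A [cap_geometry()] object.
#' @return Prefactor in mol um^-5 (negative).
#' @examples
#' dCdt_prefactor(1e-9, cap_geometry(51))  # ~ -1.41e-8
#' @export
dCdt_prefactor <- function(n0, geom = cap_geometry(51)) {
  assert_geometry(geom); assert_positive(n0, "n0")
  -1.5 * n0 / geom$c_VS
}

#' Estimate D*C0 from a measured footprint-area time series
#'
#' Inverts the constant-shrinkage law from bright-field measurements: a
#' least-squares slope `dA/dt` is converted to `dS/dt = c_SA dA/dt` and then
#' to `D*C0 = rho_w |dS/dt| / factor`, with the slope's standard error
#' propagated through the constant factors.
#'
#' @param areas Data frame with columns `time_min` (strictly increasing,
#'   >= 3 points) and `area_um2`.
#' @param geom A [cap_geometry()] object.
#' @param props A [medium_properties()] object (supplies `rho_w`).
#' @return A list with `DC0` (kg/(m s), >= 0), `se` (same units),
#'   `dAdt` and `dSdt` (um^2/min).
#' @examples
#' g <- cap_geometry(51)
#' ser <- gen_area_series(0.1, noise_frac = 0, seed = 1)
#' estimate_DC0(ser, g)$DC0  # ~1.88e-10
#' @export
estimate_DC0 <- function(areas, geom = cap_geometry(51),
                         props = medium_properties()) {
  assert_geometry(geom); assert_medium(props)
  if (!is.data.frame(areas) ||
      !all(c("time_min", "area_um2") %in% names(areas)))
    stop("`areas` needs columns `time_min` and `area_um2`", call. = FALSE)
  if (nrow(areas) < 3)
    stop("need at least 3 time points to estimate a slope", call. = FALSE)
  if (any(diff(areas$time_min) <= 0))
    stop("`time_min` must be strictly increasing", call. = FALSE)

  fit <- stats::lm(area_um2 ~ time_min, data = areas)
  slope <- unname(stats::coef(fit)["time_min"])            # um^2/min
  # a noise-free series is a legitimate input: silence the perfect-fit note
  slope_se <- unname(suppressWarnings(sqrt(diag(stats::vcov(fit))))["time_min"])
  if (slope > 0 && slope > 2 * slope_se)
    stop("area series is increasing: droplets under fresh oil cannot grow; ",
         "cannot estimate D*C0", call. = FALSE)

  dSdt <- geom$c_SA * slope
  k <- props$rho_w / (flux_balance_factor(geom) * M2_PER_S_TO_UM2_PER_MIN)
  DC0 <- max(0, -dSdt) * k
  list(DC0 = DC0, se = abs(geom$c_SA * slope_se) * k,
       dAdt = slope, dSdt = dSdt)
}

#' Initial volume whose concentration rises by a given factor
#'
#' Finds the unique initial volume `V0` for which the solute concentration
#' multiplies by `factor` within `duration` minutes, by bisection on the
#' closed-form trajectory (the concentration ratio equals the volume ratio
#' `V0 / V(duration)`). Operationalizes the observed sharp survival
#' threshold: droplets below this volume concentrate faster than the factor.
#'
#' @param duration Exposure time, min (> 0).
#' @param concentration_factor Target `C(duration)/C(0)`, > 1.
#' @param geom A [cap_geometry()] object.
#' @param props A [medium_properties()] object.
#' @return Critical initial volume in nL.
#' @examples
#' critical_volume(30, 2)  # V0 losing half its water in 30 min
#' @export
critical_volume <- function(duration = 30, concentration_factor = 2,
                            geom = cap_geometry(51),
                            props = medium_properties()) {
  assert_geometry(geom); assert_medium(props)
  assert_positive(duration, "duration")
  if (concentration_factor <= 1)
    stop("`concentration_factor` must exceed 1", call. = FALSE)
  rate <- surface_shrink_rate(props, geom)
  if (rate >= 0)
    stop("no finite critical volume: the droplet does not shrink ",
         "(saturated oil or DC0 = 0)", call. = FALSE)

  loss <- abs(rate) * duration                 # um^2 of surface lost
  ratio_of_V0 <- function(V0_nl) {
    S0 <- surface_from_volume(nl_to_um3(V0_nl), geom)
    if (S0 <= loss) return(Inf)                # vanished: infinite factor
    (S0 / (S0 - loss))^1.5
  }
  f <- function(lv) {
    r <- ratio_of_V0(exp(lv))
    if (!is.finite(r)) 1e6 else r - concentration_factor
  }
  # concentration factor decreases with V0: bracket on log-volume
  lo <- log(um3_to_nl(volume_from_surface(loss * 1.0000001, geom)))
  hi <- log(1e9)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  exp(root)
}
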