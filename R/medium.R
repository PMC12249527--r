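# Physical property containers: the aqueous medium / oil interface, the
# fluorophore used for polarization viscometry, and the ellipsoidal cell
# shape used for drag. Plain validated lists with S3 classes.

#' Properties of the aqueous medium and the oil interface
#'
#' Bundles the physical constants governing water loss from a droplet under
#' oil and the viscosity of the suspension.
#'
#' @param rho_w Density of water, kg/m^3 (default 997, at 25 C).
#' @param DC0 Product of the diffusivity of water in oil and the equilibrium
#'   water concentration in oil at the interface, kg/(m s). Only the product
#'   is identifiable; default 1.88e-10.
#' @param osmolarity Total solute content of the medium, Osm/L
#'   (default 0.15, typical for biological solutions).
#' @param saturation Oil-saturation fraction sigma in `[0, 1]`: 0 for fresh
#'   oil, 1 for water-saturated oil in which the interfacial concentration
#'   gradient (and hence all water loss) is nulled. Enters every flux as a
#'   linear factor `(1 - sigma)`.
#' @param eta_w Viscosity of water, cP (default 0.89).
#' @param eta_s0 Initial viscosity of the cell suspension, cP
#'   (default 1.876, rheometer value).
#' @return An object of class `medium_properties`.
#' @examples
#' medium_properties()                  # defaults: fresh oil
#' medium_properties(saturation = 1)    # water-saturated oil: no shrinkage
#' @export
medium_properties <- function(rho_w = 997, DC0 = 1.88e-10, osmolarity = 0.15,
                              saturation = 0, eta_w = 0.89, eta_s0 = 1.876) {
  stopifnot(is.numeric(rho_w), is.numeric(DC0), is.numeric(osmolarity),
            is.numeric(saturation), is.numeric(eta_w), is.numeric(eta_s0))
  if (rho_w <= 0) stop("`rho_w` must be positive", call. = FALSE)
  if (DC0 < 0) stop("`DC0` must be nonnegative", call. = FALSE)
  if (osmolarity <= 0) stop("`osmolarity` must be positive", call. = FALSE)
  if (saturation < 0 || saturation > 1)
    stop("`saturation` must lie in [0, 1]", call. = FALSE)
  if (eta_w <= 0) stop("`eta_w` must be positive", call. = FALSE)
  if (eta_s0 < eta_w)
    stop("`eta_s0` must be >= `eta_w` (solutes cannot lower viscosity here)",
         call. = FALSE)
  structure(
    list(rho_w = rho_w, DC0 = DC0, osmolarity = osmolarity,
         saturation = saturation, eta_w = eta_w, eta_s0 = eta_s0),
    class = "medium_properties")
}

#' @export
print.medium_properties <- function(x, ...) {
  cat("Medium / oil-interface properties\n")
  cat(sprintf("  rho_w  %g kg/m^3   D*C0  %g kg/(m s)   saturation %g\n",
              x$rho_w, x$DC0, x$saturation))
  cat(sprintf("  osmolarity %g Osm/L   eta_w %g cP   eta_s0 %g cP\n",
              x$osmolarity, x$eta_w, x$eta_s0))
  invisible(x)
}

assert_medium <- function(props) {
  if (!inherits(props, "medium_properties"))
    stop("`props` must be a medium_properties object", call. = FALSE)
  props
}

#' Fluorophore constants for Perrin-equation viscometry
#'
#' Constants of the dye used for fluorescence-polarization viscometry.
#' Defaults are the literature values for fluorescein.
#'
#' @param p0 Intrinsic polarization: the limiting polarization when no
#'   rotation occurs during the excited-state lifetime. In `(0, 0.5]`.
#' @param tau_ns Fluorescence lifetime, ns.
#' @param M_W Molar mass, g/mol.
#' @param density Fluorophore density, g/cm^3; the molar volume is
#'   `M_W / density` cm^3/mol.
#' @param T_K Temperature, K (default 298.15, room temperature).
#' @return An object of class `fluorophore_spec`.
#' @examples
#' fluorophore_spec()  # fluorescein at 25 C
#' @export
fluorophore_spec <- function(p0 = 0.5, tau_ns = 3.8, M_W = 376.3,
                             density = 1.0, T_K = 298.15) {
  if (p0 <= 0 || p0 > 0.5)
    stop("`p0` must lie in (0, 0.5]", call. = FALSE)
  for (nm in c("tau_ns", "M_W", "density", "T_K")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0)
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
  }
  structure(
    list(p0 = p0, tau_ns = tau_ns, M_W = M_W, density = density, T_K = T_K),
    class = "fluorophore_spec")
}

#' @export
print.fluorophore_spec <- function(x, ...) {
  cat(sprintf(
    "Fluorophore: p0 %g, tau %g ns, M_W %g g/mol, rho %g g/cm^3, T %g K\n",
    x$p0, x$tau_ns, x$M_W, x$density, x$T_K))
  invisible(x)
}

assert_fluorophore <- function(spec) {
  if (!inherits(spec, "fluorophore_spec"))
    stop("`spec` must be a fluorophore_spec object", call. = FALSE)
  spec
}

#' Tri-axial ellipsoid approximation of a sperm-cell head
#'
#' Semi-axes of the ellipsoid used for Stokes drag; `a` is the major
#' semi-axis along the direction of motion. Defaults are the measured head
#' dimensions a = 2.5, b = 1.0, c = 1.5 um.
#'
#' @param a,b,c Semi-axes in um, with `a >= b > 0` and `a >= c > 0`
#'   (prolate along the swimming direction).
#' @return An object of class `sperm_morphology`.
#' @examples
#' m <- sperm_morphology()
#' axis_ratio(m)  # ~2.04
#' @export
sperm_morphology <- function(a = 2.5, b = 1.0, c = 1.5) {
  if (!all(is.finite(c(a, b, c))) || b <= 0 || c <= 0)
    stop("semi-axes must be positive and finite", call. = FALSE)
  if (a < b || a < c)
    stop("`a` must be the major semi-axis (a >= b and a >= c)", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "sperm_morphology")
}

#' @export
print.sperm_morphology <- function(x, ...) {
  cat(sprintf("Ellipsoid semi-axes a = %g, b = %g, c = %g um (beta = %.3f)\n",
              x$a, x$b, x$c, x$a / sqrt(x$b * x$c)))
  invisible(x)
}

assert_morphology <- function(morph) {
  if (!inherits(morph, "sperm_morphology"))
    stop("`morph` must be a sperm_morphology object", call. = FALSE)
  morph
}
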