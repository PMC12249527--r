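# Ideal spherical-cap geometry of a sessile droplet.
#
# A droplet resting on glass with contact angle alpha is modelled as a
# spherical cap of curvature radius R. Five coefficients tie together the cap
# radius R, the curved (air/oil-facing) surface area S, the footprint
# ("cross-sectional") area A of the wetted base disk, and the volume V:
#
#   S = c_S  * R^2        c_S  = 2 pi (1 - cos a)
#   V = c_V  * R^3        c_V  = (pi/3)(2 + cos a)(1 - cos a)^2
#   S = c_SA * A          c_SA = 2 (1 - cos a) / sin^2 a
#   V = c_VS * S^(3/2)    c_VS = c_V / c_S^(3/2)
#   V = c_VA * A^(3/2)    c_VA = c_VS * c_SA^(3/2)
#
# with A = pi (R sin a)^2. Note S deliberately excludes the base disk: only
# the curved surface exchanges water with the oil. Coefficients are always
# computed from alpha, never hard-coded to their rounded 3-figure forms.

#' Spherical-cap geometry of a sessile droplet
#'
#' Constructs the full set of shape coefficients for an ideal spherical cap
#' with the given contact angle. At the measured contact angle of 51 degrees
#' the coefficients evaluate to approximately `S = 2.329 R^2`,
#' `V = 0.378 R^3`, `S = 1.228 A`, `V = 0.106 S^(3/2)` and
#' `V = 0.145 A^(3/2)`.
#'
#' @param alpha_deg Contact angle in degrees, strictly between 0 and 180.
#'   Angles are accepted in degrees everywhere in the package; radians are
#'   internal only.
#' @return An object of class `cap_geometry`: a list with `alpha_deg` and the
#'   five coefficients `c_S`, `c_V`, `c_SA`, `c_VS`, `c_VA`.
#' @examples
#' g <- cap_geometry(51)
#' g$c_S   # ~2.329
#' g$c_VA  # ~0.145
#' @export
cap_geometry <- function(alpha_deg = 51) {
  if (!is.numeric(alpha_deg) || length(alpha_deg) != 1L || !is.finite(alpha_deg))
    stop("`alpha_deg` must be a single finite number", call. = FALSE)
  if (alpha_deg <= 0 || alpha_deg >= 180)
    stop("`alpha_deg` must lie strictly between 0 and 180 degrees ",
         "(degenerate cap otherwise)", call. = FALSE)
  a <- alpha_deg * pi / 180
  cosa <- cos(a)
  sina <- sin(a)
  c_S  <- 2 * pi * (1 - cosa)
  c_V  <- (pi / 3) * (2 + cosa) * (1 - cosa)^2
  c_SA <- 2 * (1 - cosa) / sina^2
  c_VS <- c_V / c_S^1.5
  c_VA <- c_VS * c_SA^1.5
  structure(
    list(alpha_deg = alpha_deg, c_S = c_S, c_V = c_V, c_SA = c_SA,
         c_VS = c_VS, c_VA = c_VA),
    class = "cap_geometry")
}

#' @export
print.cap_geometry <- function(x, ...) {
  cat(sprintf("Spherical-cap geometry (contact angle %g deg)\n", x$alpha_deg))
  cat(sprintf("  S = %.4f R^2      V = %.4f R^3\n", x$c_S, x$c_V))
  cat(sprintf("  S = %.4f A        V = %.4f S^(3/2)   V = %.4f A^(3/2)\n",
              x$c_SA, x$c_VS, x$c_VA))
  invisible(x)
}

assert_geometry <- function(geom) {
  if (!inherits(geom, "cap_geometry"))
    stop("`geom` must be a cap_geometry object (see cap_geometry())",
         call. = FALSE)
  geom
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  x
}

#' Spherical-cap conversions between radius, areas and volume
#'
#' Forward and inverse relations between the cap radius `R`, curved surface
#' area `S`, footprint area `A` and volume `V` of a sessile droplet.
#' All lengths in micrometres, areas in um^2, volumes in um^3.
#'
#' @param R Cap radius of curvature, um (> 0).
#' @param S Curved surface area, um^2 (> 0).
#' @param A Footprint (cross-sectional) area of the base disk, um^2 (> 0).
#' @param geom A [cap_geometry()] object.
#' @return A numeric vector of the converted quantity.
#' @examples
#' g <- cap_geometry(51)
#' surface_from_radius(10, g)  # ~232.9 um^2
#' volume_from_area(100, g)    # ~145 um^3
#' @name cap_conversions
NULL

#' @rdname cap_conversions
#' @export
surface_from_radius <- function(R, geom) {
  assert_geometry(geom); assert_positive(R, "R")
  geom$c_S * R^2
}

#' @rdname cap_conversions
#' @export
volume_from_radius <- function(R, geom) {
  assert_geometry(geom); assert_positive(R, "R")
  geom$c_V * R^3
}

#' @rdname cap_conversions
#' @export
surface_from_area <- function(A, geom) {
  assert_geometry(geom); assert_positive(A, "A")
  geom$c_SA * A
}

#' @rdname cap_conversions
#' @export
area_from_surface <- function(S, geom) {
  assert_geometry(geom); assert_positive(S, "S")
  S / geom$c_SA
}

#' @rdname cap_conversions
#' @export
volume_from_surface <- function(S, geom) {
  assert_geometry(geom); assert_positive(S, "S")
  geom$c_VS * S^1.5
}

#' @rdname cap_conversions
#' @export
surface_from_volume <- function(V, geom) {
  assert_geometry(geom); assert_positive(V, "V")
  (V / geom$c_VS)^(2 / 3)
}

#' @rdname cap_conversions
#' @export
volume_from_area <- function(A, geom) {
  assert_geometry(geom); assert_positive(A, "A")
  geom$c_VA * A^1.5
}

#' @rdname cap_conversions
#' @export
radius_from_area <- function(A, geom) {
  assert_geometry(geom); assert_positive(A, "A")
  sqrt(A / pi) / sin(geom$alpha_deg * pi / 180)
}

#' @rdname cap_conversions
#' @param V Droplet volume, um^3 (> 0).
#' @export
area_from_volume <- function(V, geom) {
  assert_geometry(geom); assert_positive(V, "V")
  (V / geom$c_VA)^(2 / 3)
}
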