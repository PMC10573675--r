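#' Classical geometric stone-burden estimators
#'
#' Formula-based approximations of stone burden used before 3D volumetry,
#' provided for comparison with segmented volumes. Stones are rarely true
#' geometric solids, so these are rough: a 12 mm sphere (905 mm^3) carries
#' about 3.5 times the volume of a 20 x 5 x 5 mm ellipsoid (262 mm^3) even
#' though its maximum diameter is much smaller.
#'
#' * `sphere_volume(d)` = 4/3 * pi * (d/2)^3 for diameter `d`.
#' * `ellipsoid_volume(l, w, h)` = pi/6 * l * w * h, axes given as full
#'   lengths (diameters); reduces to `sphere_volume(d)` when all equal.
#' * `ackerman_volume(r)` = 0.6 * pi * r^2, implemented verbatim as the
#'   formula circulates; note it is dimensionally an area (mm^2), not a
#'   volume -- retained as printed for comparability.
#' * `cumulative_diameter(d)` = sum of the largest stone diameters across
#'   planes/stones; 0 for an empty list.
#' * `surface_area_estimate(d, w)` = pi/4 * d * w (mm^2), the planar
#'   ellipse-area estimate from maximum diameter and width.
#'
#' @param diameter_mm,l_mm,w_mm,h_mm,radius_mm,max_diameter_mm,width_mm
#'   linear measurements in mm; must be non-negative.
#' @param diameters_mm numeric vector of diameters in mm (possibly empty).
#' @return A numeric scalar (mm^3 for the volume formulas, mm^2 for
#'   `ackerman_volume` and `surface_area_estimate`, mm for
#'   `cumulative_diameter`).
#' @examples
#' sphere_volume(12)          # ~904.78
#' ellipsoid_volume(20, 5, 5) # ~261.80
#' cumulative_diameter(c(10, 5, 5))
#' @name geometric_estimators
NULL

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("`%s` must be non-negative and finite", what))
  x
}

#' @rdname geometric_estimators
#' @export
sphere_volume <- function(diameter_mm) {
  check_nonneg(diameter_mm, "diameter_mm")
  4 / 3 * pi * (diameter_mm / 2)^3
}

#' @rdname geometric_estimators
#' @export
ellipsoid_volume <- function(l_mm, w_mm, h_mm) {
  check_nonneg(l_mm, "l_mm"); check_nonneg(w_mm, "w_mm"); check_nonneg(h_mm, "h_mm")
  pi / 6 * l_mm * w_mm * h_mm
}

#' @rdname geometric_estimators
#' @export
ackerman_volume <- function(radius_mm) {
  check_nonneg(radius_mm, "radius_mm")
  0.6 * pi * radius_mm^2
}

#' @rdname geometric_estimators
#' @export
cumulative_diameter <- function(diameters_mm) {
  if (length(diameters_mm) == 0L) return(0)
  check_nonneg(diameters_mm, "diameters_mm")
  sum(diameters_mm)
}

#' @rdname geometric_estimators
#' @export
surface_area_estimate <- function(max_diameter_mm, width_mm) {
  check_nonneg(max_diameter_mm, "max_diameter_mm")
  check_nonneg(width_mm, "width_mm")
  pi / 4 * max_diameter_mm * width_mm
}
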