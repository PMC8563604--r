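#' Fluid properties for dimensionless-number calculations
#'
#' Bundles the density and dynamic viscosity of the process fluid, the two
#' properties entering the Reynolds number.
#'
#' @param density Fluid density in kg/m^3.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties(density = 998, viscosity = 1e-3) # water-like
#' @export
fluid_properties <- function(density, viscosity) {
  check_positive(density = density, viscosity = viscosity)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Structured insert geometry
#'
#' Describes one structured reactor insert: a monolithic support with
#' internal channels (honeycomb, straight hexagonal channels) or a repeated
#' cubic-lattice motif. The geometry drives the residence time (through the
#' internal volume), the superficial velocity and Reynolds number (through
#' the open cross-section and hydraulic diameter) and the space-time yield
#' normalization.
#'
#' If `cross_section_area` is not supplied it is derived as the effective
#' open cross-section `internal_volume / length`; if `wetted_perimeter` is
#' not supplied it is derived from the hydraulic diameter as
#' `4 * cross_section_area / hydraulic_diameter`.
#'
#' @param name Label, e.g. `"HC3"`.
#' @param family `"HC"` (honeycomb) or `"CL"` (cubic lattice).
#' @param hydraulic_diameter Hydraulic diameter in mm.
#' @param internal_volume Internal (fluid) volume in mm^3.
#' @param internal_area Internal wetted surface area in mm^2.
#' @param length Characteristic (insert) length in mm.
#' @param cross_section_area Open cross-sectional area in mm^2 (optional).
#' @param wetted_perimeter Wetted perimeter in mm (optional).
#' @param area_to_volume Declared surface-to-volume ratio in mm^2/mm^3
#'   (optional); when given it is checked against
#'   `internal_area / internal_volume` within 1%.
#' @return An object of class `insert_geometry`.
#' @examples
#' insert_library()$HC3
#' @export
insert_geometry <- function(name, family = c("HC", "CL"),
                            hydraulic_diameter, internal_volume,
                            internal_area, length,
                            cross_section_area = NULL,
                            wetted_perimeter = NULL,
                            area_to_volume = NULL) {
  family <- match.arg(family)
  check_positive(hydraulic_diameter = hydraulic_diameter,
                 internal_volume = internal_volume,
                 internal_area = internal_area, length = length)
  if (is.null(cross_section_area)) {
    cross_section_area <- internal_volume / length
  }
  check_positive(cross_section_area = cross_section_area)
  if (is.null(wetted_perimeter)) {
    wetted_perimeter <- 4 * cross_section_area / hydraulic_diameter
  }
  check_positive(wetted_perimeter = wetted_perimeter)
  if (!is.null(area_to_volume)) {
    ratio <- internal_area / internal_volume
    if (abs(ratio - area_to_volume) > 0.01 * area_to_volume) {
      stop_domain(sprintf(
        "internal_area/internal_volume = %.3f differs from declared area_to_volume = %.3f by more than 1%%",
        ratio, area_to_volume))
    }
  }
  structure(list(name = name, family = family,
                 hydraulic_diameter = hydraulic_diameter,
                 internal_volume = internal_volume,
                 internal_area = internal_area,
                 length = length,
                 cross_section_area = cross_section_area,
                 wetted_perimeter = wetted_perimeter),
            class = "insert_geometry")
}

#' @export
print.insert_geometry <- function(x, ...) {
  cat(sprintf("<insert_geometry> %s (%s)\n", x$name, x$family))
  cat(sprintf("  d_H = %.3f mm, V_i = %.2f mm^3, area = %.1f mm^2, L = %.1f mm\n",
              x$hydraulic_diameter, x$internal_volume, x$internal_area,
              x$length))
  cat(sprintf("  open cross-section = %.3f mm^2, wetted perimeter = %.2f mm\n",
              x$cross_section_area, x$wetted_perimeter))
  invisible(x)
}

#' Built-in library of 3D-printed structured inserts
#'
#' Returns the geometric characteristics of the six alumina structured
#' inserts (three honeycomb channel sizes, three cubic-lattice cell sizes),
#' all 39.8 mm long to fit an 8 mm ID HPLC column. The open cross-section
#' and wetted perimeter are derived from the tabulated volume, length and
#' hydraulic diameter (see [insert_geometry()]).
#'
#' @return A named list of [insert_geometry()] objects
#'   (`HC1`, `HC2`, `HC3`, `CL1`, `CL2`, `CL3`).
#' @export
insert_library <- function() {
  spec <- list(
    HC1 = list("HC", 0.757, 351.71, 1857.30),
    HC2 = list("HC", 0.521, 314.86, 2416.17),
    HC3 = list("HC", 0.263, 234.65, 3572.21),
    CL1 = list("CL", 1.564, 1044.78, 2671.38),
    CL2 = list("CL", 0.930, 842.98, 3627.25),
    CL3 = list("CL", 0.433, 467.12, 4319.53)
  )
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    insert_geometry(name = nm, family = s[[1]], hydraulic_diameter = s[[2]],
                    internal_volume = s[[3]], internal_area = s[[4]],
                    length = 39.8)
  })
  names(out) <- names(spec)
  out
}

#' Hydraulic diameter of a non-circular channel
#'
#' `d_H = 4 A / P`, the characteristic length used in the Reynolds number
#' for arbitrary channel cross-sections.
#'
#' @param area Cross-sectional area (any length unit squared).
#' @param perimeter Wetted perimeter (same length unit).
#' @return Hydraulic diameter in the same length unit.
#' @examples
#' hydraulic_diameter(pi * 0.5^2, pi * 1) # circle of diameter 1
#' @export
hydraulic_diameter <- function(area, perimeter) {
  check_positive(area = area, perimeter = perimeter)
  4 * area / perimeter
}

#' Channel Reynolds number
#'
#' `Re = rho u d_H / mu` with all quantities in SI units.
#'
#' @param fluid A [fluid_properties()] object.
#' @param velocity Superficial velocity in m/s.
#' @param hydraulic_diameter Hydraulic diameter in m.
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(fluid, velocity, hydraulic_diameter) {
  stopifnot(inherits(fluid, "fluid_properties"))
  check_positive(velocity = velocity,
                 hydraulic_diameter = hydraulic_diameter)
  fluid$density * velocity * hydraulic_diameter / fluid$viscosity
}

# Superficial velocity (m/s) from a flowrate in mL/min through an open
# cross-section in mm^2: 1 mL/min = 1e-6/60 m^3/s, 1 mm^2 = 1e-6 m^2.
superficial_velocity <- function(flowrate, cross_section_area) {
  check_positive(flowrate = flowrate,
                 cross_section_area = cross_section_area)
  flowrate / (60 * cross_section_area)
}
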