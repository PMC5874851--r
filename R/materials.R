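## Material descriptions and range-shifter geometry.

#' Slab material description
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3 (> 0).
#' @param radiation_length_mass Radiation length in g/cm^2 (> 0).
#' @param range_coeff_alpha Bragg-Kleeman coefficient alpha' in cm/MeV^p.
#' @param range_exponent_p Bragg-Kleeman exponent p, in (1, 2.5).
#' @return An object of class `material`.
#' @export
material <- function(name, density, radiation_length_mass,
                     range_coeff_alpha, range_exponent_p) {
  stopifnot(density > 0, radiation_length_mass > 0, range_coeff_alpha > 0)
  if (range_exponent_p <= 1 || range_exponent_p >= 2.5)
    stop("range exponent p must lie in (1, 2.5)")
  structure(list(name = name, density = density,
                 radiation_length_mass = radiation_length_mass,
                 range_coeff_alpha = range_coeff_alpha,
                 range_exponent_p = range_exponent_p),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: rho = %.3f g/cm^3, X0 = %.2f g/cm^2, R = %.6g E^%.4f cm\n",
              x$name, x$density, x$radiation_length_mass,
              x$range_coeff_alpha, x$range_exponent_p))
  invisible(x)
}

#' Load the material registry
#'
#' Reads a YAML registry of materials. The registry shipped with the package
#' contains water and Lexan (polycarbonate); the Bragg-Kleeman coefficients
#' stored there were fitted once against ranges computed by Bethe
#' stopping-power integration (see `tools/make_materials.R` in the source
#' tree) and are cross-checked by the test suite.
#'
#' @param path Path to a YAML file; defaults to the shipped registry.
#' @return Named list of [material()] objects.
#' @export
load_material_registry <- function(path = system.file("extdata", "materials.yaml",
                                                      package = "rsbeam")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(m) {
    material(m$name, m$density, m$radiation_length_mass,
             m$range_coeff_alpha, m$range_exponent_p)
  })
  names(out) <- vapply(out, function(m) m$name, character(1))
  out
}

the_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_material_registry()
    cache
  }
})

#' Look up a shipped material
#'
#' @param name `"water"` or `"lexan"`.
#' @return A [material()] object from the shipped registry.
#' @export
get_material <- function(name) {
  reg <- the_registry()
  if (!name %in% names(reg)) {
    stop("unknown material '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Range-shifter setup
#'
#' Physical description and position of a range-shifter slab. The
#' water-equivalent thickness (WET) is computed from range ratios at a
#' reference energy when not supplied: WET = R_water(E_ref) - R_water(E_out),
#' where E_out is the exit energy after traversing the physical slab.
#'
#' @param material A [material()] object (the slab medium).
#' @param physical_thickness Physical thickness in cm (> 0).
#' @param downstream_face_position Downstream face position, cm from isocenter
#'   (positive toward the nozzle, > 0).
#' @param wet Water-equivalent thickness in cm; computed if `NULL`.
#' @param position_convention Snout-position convention used to derive the
#'   face position (informational; see [snout_to_rs()]).
#' @param wet_reference_energy Energy (MeV) at which WET is evaluated; the
#'   dependence on this choice is a few parts in 10^3 over the clinical range.
#' @param water Water material used for the WET computation.
#' @return An object of class `rs_setup`.
#' @export
rs_setup <- function(material, physical_thickness, downstream_face_position,
                     wet = NULL,
                     position_convention = "eclipse_downstream_face",
                     wet_reference_energy = 160,
                     water = get_material("water")) {
  stopifnot(inherits(material, "material"),
            physical_thickness > 0, downstream_face_position > 0)
  if (is.null(wet)) {
    wet <- wet_of_slab(material, physical_thickness,
                       E_ref = wet_reference_energy, water = water)
  }
  stopifnot(wet > 0)
  structure(list(material = material,
                 physical_thickness = physical_thickness,
                 wet = wet,
                 downstream_face_position = downstream_face_position,
                 position_convention = position_convention),
            class = "rs_setup")
}

#' @export
print.rs_setup <- function(x, ...) {
  cat(sprintf("<rs_setup> %.2f cm %s (WET %.3f cm), downstream face %.1f cm from isocenter\n",
              x$physical_thickness, x$material$name, x$wet,
              x$downstream_face_position))
  invisible(x)
}

#' Water-equivalent thickness of a slab
#'
#' WET from range ratios: the water-range loss matching the slab's energy
#' loss at a reference energy.
#'
#' @inheritParams rs_setup
#' @param E_ref Reference energy in MeV.
#' @return WET in cm.
#' @export
wet_of_slab <- function(material, physical_thickness, E_ref = 160,
                        water = get_material("water")) {
  e_out <- energy_at_depth(E_ref, physical_thickness, material)
  range_of_energy(E_ref, water) - range_of_energy(e_out, water)
}
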