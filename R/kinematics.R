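## Relativistic proton kinematics and range-energy relations.
## Units throughout: MeV, cm, g/cm^2, rad. Proton rest energy fixed at the
## CODATA value; all operations are vectorized over energy.

#' Proton rest energy
#'
#' @return The proton rest energy in MeV (938.272).
#' @export
proton_rest_mass <- function() 938.272

#' Kinematic factor pv
#'
#' The product of particle momentum and velocity, `pv = E(E + 2*E0)/(E + E0)`,
#' which sets the multiple-Coulomb-scattering strength scale.
#'
#' @param E Kinetic energy in MeV (vectorized, must be >= 0).
#' @param rest_mass Rest energy E0 in MeV.
#' @return pv in MeV; strictly increasing in `E`, zero iff `E = 0`.
#' @export
kinematic_factor <- function(E, rest_mass = proton_rest_mass()) {
  if (any(E < 0)) stop("kinetic energy must be nonnegative")
  E * (E + 2 * rest_mass) / (E + rest_mass)
}

#' Proton speed as a fraction of c
#'
#' @inheritParams kinematic_factor
#' @return beta = sqrt(1 - (E0/(E + E0))^2), in [0, 1).
#' @export
beta_of_energy <- function(E, rest_mass = proton_rest_mass()) {
  if (any(E < 0)) stop("kinetic energy must be nonnegative")
  gamma <- (E + rest_mass) / rest_mass
  sqrt(1 - 1 / gamma^2)
}

#' Kinetic energy from beta
#'
#' Inverse of [beta_of_energy()].
#'
#' @param beta Speed fraction in [0, 1).
#' @inheritParams kinematic_factor
#' @return Kinetic energy in MeV.
#' @export
energy_of_beta <- function(beta, rest_mass = proton_rest_mass()) {
  if (any(beta < 0 | beta >= 1)) stop("beta must lie in [0, 1)")
  rest_mass * (1 / sqrt(1 - beta^2) - 1)
}

#' Bethe electronic stopping power
#'
#' Mean electronic stopping power for protons from the Bethe formula without
#' shell or density corrections, adequate above a few MeV. Used to build the
#' reference range table from which the Bragg-Kleeman power law is fitted.
#'
#' @param E Kinetic energy in MeV.
#' @param z_over_a Ratio of atomic number to atomic mass of the medium (mol/g).
#' @param i_excitation_ev Mean excitation energy in eV.
#' @inheritParams kinematic_factor
#' @return Mass stopping power in MeV cm^2/g.
#' @export
bethe_stopping_power <- function(E, z_over_a, i_excitation_ev,
                                 rest_mass = proton_rest_mass()) {
  K <- 0.307075            # 4 pi N_A r_e^2 m_e c^2, MeV cm^2/mol
  me <- 0.510999           # electron rest energy, MeV
  beta2 <- beta_of_energy(E, rest_mass)^2
  gamma2 <- ((E + rest_mass) / rest_mass)^2
  K * z_over_a / beta2 * (log(2 * me * beta2 * gamma2 / (i_excitation_ev * 1e-6)) - beta2)
}

#' CSDA range by stopping-power integration
#'
#' Continuous-slowing-down range obtained by integrating the inverse Bethe
#' stopping power from a 2 MeV cutoff (the residual range below the cutoff is
#' negligible at therapeutic energies).
#'
#' @inheritParams bethe_stopping_power
#' @param density Mass density in g/cm^3.
#' @return Range in cm.
#' @export
csda_range <- function(E, z_over_a, i_excitation_ev, density,
                       rest_mass = proton_rest_mass()) {
  f <- function(e) 1 / bethe_stopping_power(e, z_over_a, i_excitation_ev, rest_mass)
  vapply(E, function(e) {
    if (e <= 2) return(0)
    stats::integrate(f, 2, e, rel.tol = 1e-10)$value
  }, numeric(1)) / density
}

#' Fit a Bragg-Kleeman power law
#'
#' Least-squares fit of `log R = log alpha + p log E` to a range-energy table.
#'
#' @param energies Kinetic energies in MeV.
#' @param ranges Ranges in cm.
#' @return List with `alpha` (cm/MeV^p) and `p` (dimensionless).
#' @export
fit_range_law <- function(energies, ranges) {
  co <- stats::coef(stats::lm(log(ranges) ~ log(energies)))
  list(alpha = unname(exp(co[1])), p = unname(co[2]))
}

#' Range from energy (Bragg-Kleeman law)
#'
#' @param E Kinetic energy in MeV.
#' @param material A [material()] object.
#' @return Range `alpha * E^p` in cm.
#' @export
range_of_energy <- function(E, material) {
  if (any(E < 0)) stop("kinetic energy must be nonnegative")
  material$range_coeff_alpha * E^material$range_exponent_p
}

#' Residual energy after a slab depth
#'
#' Inverts the Bragg-Kleeman law: the energy whose residual range equals the
#' incident range minus `depth`.
#'
#' @param E_in Incident kinetic energy in MeV.
#' @param depth Depth in the material in cm; must not exceed the range.
#' @param material A [material()] object.
#' @return Exit kinetic energy in MeV.
#' @export
energy_at_depth <- function(E_in, depth, material) {
  if (any(depth < 0)) stop("depth must be nonnegative")
  res <- range_of_energy(E_in, material) - depth
  if (any(res < -1e-12)) {
    stop("stopped: beam range ", signif(range_of_energy(E_in, material), 6),
         " cm is less than depth ", signif(max(depth), 6), " cm")
  }
  (pmax(res, 0) / material$range_coeff_alpha)^(1 / material$range_exponent_p)
}

#' Translate a snout position to the range-shifter downstream face position
#'
#' Planning and delivery systems disagree on what "snout position" refers to.
#' Under the Eclipse default the snout position already is the downstream face
#' of the range shifter; under the IBA convention the snout position is the
#' upstream face (the RS is mounted on the aperture holder), so the downstream
#' face sits one physical thickness closer to isocenter; the Hitachi/MDACC
#' convention likewise requires a physical-thickness offset between the snout
#' position and the downstream face.
#'
#' @param snout_position Snout position, cm from isocenter (positive toward
#'   the nozzle).
#' @param physical_thickness Physical RS thickness in cm.
#' @param convention One of `"eclipse_downstream_face"`, `"iba_upstream_face"`,
#'   `"hitachi_snout_face"`.
#' @return Downstream face position, cm from isocenter.
#' @export
snout_to_rs <- function(snout_position, physical_thickness,
                        convention = c("eclipse_downstream_face",
                                       "iba_upstream_face",
                                       "hitachi_snout_face")) {
  convention <- match.arg(convention)
  if (any(snout_position <= 0)) stop("snout position must be positive")
  out <- switch(convention,
    eclipse_downstream_face = snout_position,
    iba_upstream_face       = snout_position - physical_thickness,
    hitachi_snout_face      = snout_position - physical_thickness
  )
  if (any(out <= 0)) stop("geometry error: range shifter would cross isocenter")
  out
}

## Coordinate convention helpers. Public positions are quoted in cm from
## isocenter, positive toward the nozzle (the measurement convention).
## Internally a propagation coordinate increases along the beam direction
## with isocenter at 0, so the two differ by a sign.

#' Convert between isocenter and beam-propagation coordinates
#'
#' Measurement positions are quoted as cm from isocenter, positive toward the
#' nozzle. The internal propagation coordinate increases along the beam
#' direction (downstream positive) with isocenter at zero. The map is its own
#' inverse (a sign flip).
#'
#' @param z Position(s) in cm.
#' @return The same position(s) in the other convention.
#' @export
iso_to_beam <- function(z) -z

#' @rdname iso_to_beam
#' @export
beam_to_iso <- function(z) -z
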