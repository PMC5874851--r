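## Multiple-Coulomb-scattering widths and Fermi-Eyges moment increments for a
## range-shifter slab.

#' Highland multiple-scattering angle
#'
#' Gaussian-core width of the projected multiple-Coulomb-scattering angle,
#' `theta = (14.1/pv) sqrt(L/LR) (1 + (1/9) log10(L/LR))`. The logarithmic
#' correction can be switched off; the analytical slab integrals in this
#' package exclude it by default, following Gottschalk's procedure.
#'
#' @param pv Kinematic factor in MeV (> 0).
#' @param mass_thickness Mass thickness L in g/cm^2 (>= 0).
#' @param radiation_length_mass Radiation length LR in g/cm^2.
#' @param log_correction Apply the `(1 + (1/9) log10(L/LR))` factor?
#' @return Scattering angle sigma in rad. Zero thickness gives zero.
#' @export
highland_sigma <- function(pv, mass_thickness, radiation_length_mass,
                           log_correction = TRUE) {
  if (any(pv <= 0)) stop("pv must be positive")
  if (any(mass_thickness < 0)) stop("mass thickness must be nonnegative")
  ratio <- mass_thickness / radiation_length_mass
  fac <- ifelse(ratio > 0 & log_correction, 1 + log10(pmax(ratio, .Machine$double.xmin)) / 9, 1)
  ifelse(ratio == 0, 0, 14.1 / pv * sqrt(ratio) * fac)
}

#' Lynch-Dahl multiple-scattering angle
#'
#' Gaussian fit to the core of the full Moliere distribution,
#' `theta0 = (13.6/pv) sqrt(x/X0) (1 + 0.038 ln(x/X0))`.
#'
#' @inheritParams highland_sigma
#' @param x_over_X0 Thickness in radiation lengths (> 0).
#' @return Scattering angle sigma in rad.
#' @export
lynch_dahl_sigma <- function(pv, x_over_X0) {
  if (any(pv <= 0)) stop("pv must be positive")
  if (any(x_over_X0 <= 0)) stop("x/X0 must be positive")
  13.6 / pv * sqrt(x_over_X0) * (1 + 0.038 * log(x_over_X0))
}

#' Scattering-moment increments
#'
#' The additive Fermi-Eyges increments (dA, dB, dC) a scattering element
#' contributes to the phase-space moments at a reference plane. They satisfy
#' the Cauchy-Schwarz relation dB^2 <= dA * dC.
#'
#' @param delta_A Position-variance increment, cm^2.
#' @param delta_B Covariance increment, cm rad.
#' @param delta_C Angular-variance increment, rad^2.
#' @return Object of class `scattering_moments`.
#' @export
scattering_moments <- function(delta_A, delta_B, delta_C) {
  stopifnot(delta_A >= 0, delta_C >= 0)
  if (delta_B^2 > delta_A * delta_C * (1 + 1e-9) + 1e-300)
    stop("invalid moments: delta_B^2 exceeds delta_A * delta_C")
  structure(list(delta_A = delta_A, delta_B = delta_B, delta_C = delta_C),
            class = "scattering_moments")
}

#' @export
print.scattering_moments <- function(x, ...) {
  cat(sprintf("<scattering_moments> dA = %.4g cm^2, dB = %.4g cm rad, dC = %.4g rad^2\n",
              x$delta_A, x$delta_B, x$delta_C))
  invisible(x)
}

#' Fermi-Eyges moment increments of a range-shifter slab
#'
#' Numerical quadrature of the Highland scattering power over the slab depth:
#' \deqn{\Delta A = 14.1^2 f^2 \int_0^t (t + S - z)^2 \frac{\rho}{L_R}
#'       \frac{dz}{pv(z)^2},}
#' with the first and zeroth powers of the lever arm for \eqn{\Delta B} and
#' \eqn{\Delta C}. Here `t` is the physical slab thickness, `S` the air gap
#' from the downstream face to the reference plane, and `pv(z)` follows the
#' Bragg-Kleeman slowing-down in the slab material. The Highland logarithmic
#' factor `f` is applied (optionally) once on the full slab mass thickness,
#' never per quadrature step.
#'
#' @param E_in Incident kinetic energy in MeV; the beam must exit the slab.
#' @param rs An [rs_setup()].
#' @param S Distance in cm from the slab downstream face to the reference
#'   plane (>= 0), measured downstream.
#' @param log_correction Apply the Highland log factor on the full slab?
#'   Default `FALSE` (excluded from all integrals, the analytical-reference
#'   convention).
#' @param rel_tol Quadrature relative tolerance.
#' @return A [scattering_moments()] object.
#' @export
rs_fermi_eyges_moments <- function(E_in, rs, S, log_correction = FALSE,
                                   rel_tol = 1e-10) {
  stopifnot(inherits(rs, "rs_setup"), S >= 0)
  fe_slab_moments(E_in, rs$material, rs$physical_thickness, S,
                  log_correction = log_correction, rel_tol = rel_tol)
}

## core quadrature shared with the piecewise envelope (partial thickness)
fe_slab_moments <- function(E_in, m, t, S, log_correction = FALSE,
                            rel_tol = 1e-10) {
  if (range_of_energy(E_in, m) <= t)
    stop("stopped: beam does not exit the ", t, " cm ", m$name, " slab")
  ratio_full <- m$density * t / m$radiation_length_mass
  pref <- (14.1 * (if (log_correction) 1 + log10(ratio_full) / 9 else 1))^2
  inv_pv2 <- function(z) {
    1 / kinematic_factor(energy_at_depth(E_in, z, m))^2
  }
  moment <- function(k) {
    f <- function(z) (t + S - z)^k * (m$density / m$radiation_length_mass) * inv_pv2(z)
    pref * stats::integrate(f, 0, t, rel.tol = rel_tol, subdivisions = 500L)$value
  }
  scattering_moments(moment(2), moment(1), moment(0))
}

#' Piecewise Fermi-Eyges envelope with a range shifter
#'
#' The physically correct sigma(z) at arbitrary planes: the open-beam
#' envelope upstream of the slab, partial-depth moment integrals for planes
#' inside the slab, and full-slab moments with the proper air-gap lever arm
#' downstream. This is the analytical reference the Monte Carlo benchmark
#' is compared against; note it is not the quadratic extrapolation a
#' planning system draws through the downstream envelope.
#'
#' @param ps_open Open-beam [phase_space()].
#' @param E Beam energy in MeV.
#' @param rs An [rs_setup()], or `NULL` for the open beam.
#' @param z Plane positions, beam coordinate in cm (vectorized).
#' @param log_correction Passed to the moment integrals.
#' @return sigma in cm at each plane.
#' @export
fe_sigma_envelope <- function(ps_open, E, rs = NULL, z,
                              log_correction = FALSE) {
  if (is.null(rs)) return(sigma_at(ps_open, z))
  s_face <- iso_to_beam(rs$downstream_face_position)
  s_up <- s_face - rs$physical_thickness
  vapply(z, function(zi) {
    if (zi <= s_up) return(sigma_at(ps_open, zi))
    d <- min(zi - s_up, rs$physical_thickness)
    S <- max(zi - s_face, 0)
    mom <- fe_slab_moments(E, rs$material, d, S,
                           log_correction = log_correction)
    ps_z <- free_drift(ps_open, zi - ps_open$z_ref)
    sigma_at(transport_with_scattering(ps_z, mom), zi)
  }, numeric(1))
}
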