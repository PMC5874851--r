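## Fermi-Eyges phase space of one transverse axis: second moments (A, B, C)
## at a reference plane, and their transport.
##
## Coordinates: `z_ref` and all drift arguments are in the internal
## beam-propagation coordinate (increases downstream, isocenter at 0; see
## iso_to_beam()). B is the covariance of position with the slope taken with
## respect to that coordinate.

#' Construct a phase space
#'
#' The Fermi-Eyges second moments of one transverse axis at a reference
#' plane: position variance moment A, position-angle covariance moment B and
#' angular variance moment C. Under the `"variance"` convention
#' `sigma^2 = A`; under `"eclipse_cylindrical"` the stored moments are twice
#' the variances (`A = 2 sigma^2`), the factor-two trap flagged by planning
#' documentation.
#'
#' @param A Position variance moment, cm^2 (>= 0).
#' @param B Covariance moment, cm rad.
#' @param C Angular variance moment, rad^2 (>= 0).
#' @param z_ref Reference plane, beam coordinate in cm (downstream positive,
#'   isocenter 0).
#' @param axis `"x"` or `"y"`.
#' @param convention `"variance"` or `"eclipse_cylindrical"`.
#' @param check_emittance If `TRUE`, fail when `A*C - B^2 < 0` (useful when
#'   constructing from fits).
#' @return Object of class `phase_space`.
#' @export
phase_space <- function(A, B, C, z_ref = 0, axis = c("x", "y"),
                        convention = c("variance", "eclipse_cylindrical"),
                        check_emittance = FALSE) {
  axis <- match.arg(axis)
  convention <- match.arg(convention)
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), A >= 0, C >= 0)
  if (check_emittance && A * C - B^2 < 0)
    stop("nonphysical phase space: determinant A*C - B^2 = ", A * C - B^2, " < 0")
  structure(list(A = A, B = B, C = C, z_ref = z_ref, axis = axis,
                 convention = convention),
            class = "phase_space")
}

#' @export
print.phase_space <- function(x, ...) {
  cat(sprintf("<phase_space %s, %s> A = %.5g cm^2, B = %.5g cm rad, C = %.5g rad^2 at z_ref = %g cm\n",
              x$axis, x$convention, x$A, x$B, x$C, x$z_ref))
  invisible(x)
}

conv_factor <- function(ps) if (ps$convention == "eclipse_cylindrical") 2 else 1

#' Free drift of a phase space
#'
#' Moves the reference plane by `dz` along the beam direction with no
#' material in between: `A' = C dz^2 + 2 B dz + A`, `B' = C dz + B`,
#' `C' = C`. Negative `dz` back-projects upstream (used to build the Monte
#' Carlo source plane). The emittance `A C - B^2` is exactly conserved.
#'
#' @param ps A [phase_space()].
#' @param dz Drift length in cm (beam coordinate; may be negative).
#' @return The drifted [phase_space()].
#' @export
free_drift <- function(ps, dz) {
  A2 <- ps$C * dz^2 + 2 * ps$B * dz + ps$A
  if (A2 < 0)
    stop("nonphysical phase space after drift: A(z) = ", A2,
         " < 0 (determinant ", ps$A * ps$C - ps$B^2, ")")
  phase_space(A2, ps$C * dz + ps$B, ps$C, z_ref = ps$z_ref + dz,
              axis = ps$axis, convention = ps$convention)
}

#' Add scattering moments and drift
#'
#' Adds the increments (dA, dB, dC) of a scattering element -- evaluated at
#' the same reference plane as `ps` -- and then applies an optional free
#' drift. With zero moments this reduces exactly to [free_drift()]. Under the
#' `eclipse_cylindrical` convention the increments (which are variances) are
#' doubled to match the stored moment scale.
#'
#' @param ps A [phase_space()].
#' @param moments A [scattering_moments()] referenced to `ps$z_ref`.
#' @param dz_drift_after Drift in cm applied after the addition.
#' @return The transported [phase_space()].
#' @export
transport_with_scattering <- function(ps, moments, dz_drift_after = 0) {
  stopifnot(inherits(moments, "scattering_moments"))
  k <- conv_factor(ps)
  out <- phase_space(ps$A + k * moments$delta_A,
                     ps$B + k * moments$delta_B,
                     ps$C + k * moments$delta_C,
                     z_ref = ps$z_ref, axis = ps$axis,
                     convention = ps$convention)
  if (dz_drift_after != 0) out <- free_drift(out, dz_drift_after) else out
}

#' Spot sigma at a plane
#'
#' Evaluates the beam envelope `sigma(z)` by drifting the quadratic moment to
#' plane `z`: `sigma = sqrt(A(z))` under the variance convention,
#' `sqrt(A(z)/2)` under `eclipse_cylindrical`.
#'
#' @param ps A [phase_space()].
#' @param z Plane position(s), beam coordinate in cm (vectorized).
#' @return sigma in cm.
#' @export
sigma_at <- function(ps, z) {
  dz <- z - ps$z_ref
  A <- ps$C * dz^2 + 2 * ps$B * dz + ps$A
  if (any(A < 0))
    stop("nonphysical phase space: A(z) < 0 at z = ",
         paste(z[A < 0], collapse = ", "),
         " (determinant ", ps$A * ps$C - ps$B^2, ")")
  sqrt(A / conv_factor(ps))
}

#' Emittance (covariance determinant)
#'
#' `A*C - B^2`, proportional to the squared minimum attainable spot size in
#' free drift; invariant under [free_drift()] and nonnegative for a physical
#' beam.
#'
#' @param ps A [phase_space()].
#' @return Determinant in cm^2 rad^2 (moment scale of the stored convention).
#' @export
emittance <- function(ps) ps$A * ps$C - ps$B^2
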