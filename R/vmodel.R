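## The TPS-style V-parameter range-shifter model: scattering of the slab is
## described by a single commissioned constant V, with depth dependence
## carried by the five-thirds integrals phi, chi, psi evaluated at the
## entrance and exit speeds.

#' V-parameter model description
#'
#' Parameters of the V-parameter range-shifter model. `V` is the
#' commissioned scattering constant (MeV-scale); `alpha_53` the material
#' factor of the five-thirds approximation in MeV/cm. When `alpha_53` is
#' `NULL` (default) the factor is derived per evaluation from the model's own
#' change of variables, `alpha = E0 (w(beta_i) - w(beta_o)) / L`, which makes
#' the predicted increments exactly independent of the arbitrary cutoff
#' `beta_cut`; a numeric value fixes it instead. `lynch_dahl_correction` is a
#' multiplicative correction applied to V (1 = off); the vendor's exact use
#' of the Lynch-Dahl formula is not disclosed, so it is exposed as a plain
#' factor.
#'
#' @param V Scattering constant (>= 0, may be `NA` before commissioning).
#' @param L_wet Water-equivalent thickness of the range shifter, cm.
#' @param S_reference Commissioning air gap (downstream face to reference
#'   plane), cm.
#' @param alpha_53 Five-thirds material factor in MeV/cm, or `NULL` for the
#'   self-consistent per-evaluation value.
#' @param beta_cut Lower cutoff of the five-thirds integrals.
#' @param lynch_dahl_correction Multiplicative correction factor on V.
#' @param water Water material for the WET slowing-down relation.
#' @return Object of class `vmodel`.
#' @export
vmodel <- function(V = NA_real_, L_wet, S_reference,
                   alpha_53 = NULL, beta_cut = 0.05,
                   lynch_dahl_correction = 1,
                   water = get_material("water")) {
  stopifnot(is.na(V) || V >= 0, L_wet > 0, S_reference >= 0,
            beta_cut > 0, beta_cut < 1, lynch_dahl_correction > 0)
  structure(list(V = V, L_wet = L_wet, S_reference = S_reference,
                 alpha_53 = alpha_53, beta_cut = beta_cut,
                 lynch_dahl_correction = lynch_dahl_correction,
                 water = water),
            class = "vmodel")
}

#' @export
print.vmodel <- function(x, ...) {
  cat(sprintf("<vmodel> V = %s, L = %.3f cm WET, S_ref = %.1f cm, beta_cut = %g, alpha = %s\n",
              if (is.na(x$V)) "(uncommissioned)" else format(x$V, digits = 6),
              x$L_wet, x$S_reference, x$beta_cut,
              if (is.null(x$alpha_53)) "self-consistent" else format(x$alpha_53)))
  invisible(x)
}

## entrance/exit beta and five-thirds values for one (E, L); shared by
## vmodel_deltas and extract_v
vmodel_kinematics <- function(vm, E, L) {
  E0 <- proton_rest_mass()
  E_out <- energy_at_depth(E, L, vm$water)  # errors "stopped" if L > range
  if (E_out <= 0) stop("stopped: beam does not exit the range shifter")
  b <- c(o = beta_of_energy(E_out), i = beta_of_energy(E))
  ft <- five_thirds_integrals(unname(b), beta_cut = vm$beta_cut)
  alpha <- if (is.null(vm$alpha_53)) E0 * (ft$w[2] - ft$w[1]) / L else vm$alpha_53
  list(beta_i = b[["i"]], beta_o = b[["o"]],
       phi_i = ft$phi[2], phi_o = ft$phi[1],
       chi_i = ft$chi[2], chi_o = ft$chi[1],
       psi_i = ft$psi[2], psi_o = ft$psi[1],
       alpha = alpha, E0 = E0)
}

## the three printed combinations at V = 1 (no Lynch-Dahl factor)
vmodel_unit_deltas <- function(vm, E, L, S) {
  k <- vmodel_kinematics(vm, E, L)
  a <- k$alpha; E0 <- k$E0
  dA <- 1 / (a^3 * E0) *
    (a^2 * ((S + L)^2 * k$phi_i - S^2 * k$phi_o) -
       2 * a * E0 * ((S + L) * k$chi_i - S * k$chi_o) +
       2 * E0^2 * (k$psi_i - k$psi_o))
  dB <- 1 / (a^2 * E0) *
    (a * ((S + L) * k$phi_i - S * k$phi_o) - E0 * (k$chi_i - k$chi_o))
  dC <- 1 / (a * E0) * (k$phi_i - k$phi_o)
  c(dA = dA, dB = dB, dC = dC)
}

#' Phase-space increments predicted by the V-parameter model
#'
#' Evaluates the model's (dA, dB, dC) for a beam of energy `E` crossing a
#' range shifter of water-equivalent thickness `L` whose downstream face sits
#' `S` cm upstream of the reference plane. The entrance speed comes from `E`;
#' the exit speed from slowing down through `L` of water equivalent.
#'
#' @param vm A commissioned [vmodel()] (finite `V`).
#' @param E Beam energy in MeV.
#' @param L Water-equivalent thickness in cm (default: the commissioned
#'   `L_wet`). `L = 0` gives zero increments.
#' @param S Air gap from downstream face to reference plane, cm (>= 0).
#' @return A [scattering_moments()] object.
#' @export
vmodel_deltas <- function(vm, E, L = vm$L_wet, S) {
  stopifnot(inherits(vm, "vmodel"), L >= 0, S >= 0)
  if (is.na(vm$V)) stop("vmodel is not commissioned: V is NA")
  if (L == 0 || vm$V == 0) return(scattering_moments(0, 0, 0))
  u <- vmodel_unit_deltas(vm, E, L, S)
  v_eff <- vm$V * vm$lynch_dahl_correction
  scattering_moments(v_eff * u[["dA"]], v_eff * u[["dB"]], v_eff * u[["dC"]])
}

#' Extract the V parameter from a with/without-RS phase-space pair
#'
#' Solves each of the three model equations (linear in V) for V from the
#' observed increments `ps_rs - ps_open`, both referenced at the same plane
#' (`S_reference` downstream of the RS face). Returns the three per-equation
#' estimates, their spread and their mean; a commissioning across energies is
#' assembled by [commission_vmodel()].
#'
#' @param ps_open,ps_rs [phase_space()] objects at the same reference plane
#'   and convention, without and with the range shifter.
#' @param vm_template A [vmodel()] carrying `L_wet`, `S_reference`,
#'   `beta_cut`, `alpha_53` and the Lynch-Dahl factor.
#' @param E Beam energy in MeV.
#' @return List of class `v_estimate`: `per_equation` (named A/B/C), `mean`,
#'   `spread` (max minus min), and the inputs used.
#' @export
extract_v <- function(ps_open, ps_rs, vm_template, E) {
  stopifnot(inherits(ps_open, "phase_space"), inherits(ps_rs, "phase_space"))
  if (ps_open$convention != ps_rs$convention)
    stop("convention mismatch between open and with-RS phase spaces")
  if (abs(ps_open$z_ref - ps_rs$z_ref) > 1e-9)
    stop("phase spaces must share the reference plane")
  k <- conv_factor(ps_open)
  obs <- c(dA = (ps_rs$A - ps_open$A) / k,
           dB = (ps_rs$B - ps_open$B) / k,
           dC = (ps_rs$C - ps_open$C) / k)
  if (all(abs(obs) < 1e-300)) {
    per <- c(A = 0, B = 0, C = 0)
    return(structure(list(per_equation = per, mean = 0, spread = 0, E = E),
                     class = "v_estimate"))
  }
  u <- vmodel_unit_deltas(vm_template, E, vm_template$L_wet,
                          vm_template$S_reference)
  if (any(abs(u) < 1e-300))
    stop("division by zero extracting V: unit model increment vanished (",
         paste(sprintf("%s=%.3g", names(u), u), collapse = ", "), ")")
  per <- unname(obs) / unname(u) / vm_template$lynch_dahl_correction
  names(per) <- c("A", "B", "C")
  structure(list(per_equation = per, mean = mean(per),
                 spread = max(per) - min(per), E = E),
            class = "v_estimate")
}

#' @export
print.v_estimate <- function(x, ...) {
  cat(sprintf("<v_estimate E = %g MeV> A: %.5g  B: %.5g  C: %.5g  (mean %.5g)\n",
              x$E, x$per_equation[["A"]], x$per_equation[["B"]],
              x$per_equation[["C"]], x$mean))
  invisible(x)
}

#' Predict the with-RS phase space
#'
#' Componentwise addition of the model increments to the open-beam phase
#' space at its reference plane. At the commissioning geometry
#' (`S = S_reference`, `L = L_wet`) this reproduces the commissioning with-RS
#' phase space when the data were generated by the model itself.
#'
#' @param ps_open Open-beam [phase_space()] referenced `S` cm downstream of
#'   the RS face.
#' @param vm A commissioned [vmodel()].
#' @param E Beam energy in MeV.
#' @param L Water-equivalent thickness, cm.
#' @param S Air gap to the reference plane, cm.
#' @return The predicted with-RS [phase_space()].
#' @export
predict_with_rs <- function(ps_open, vm, E, L = vm$L_wet, S = vm$S_reference) {
  transport_with_scattering(ps_open, vmodel_deltas(vm, E, L = L, S = S))
}
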