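## Commissioning-side computations: constrained phase-space fits from spot
## data, multi-energy V commissioning, and explicit emulations of two known
## Eclipse v11 defects (parameter clamping; envelope-comparison discard).

#' Fit phase-space moments to a sigma(z) profile
#'
#' Least-squares fit of the quadratic envelope
#' `sigma(z)^2 * k = C z^2 + 2 B z + A` (k = 1 for the variance convention,
#' 2 for `eclipse_cylindrical`) to spot sigmas measured at three or more
#' planes. With `enforce_constraint` the fit is restricted to the physical
#' cone `A >= 0, C >= 0, A C - B^2 >= 0`; because that set is the 2x2
#' positive-semidefinite cone and the objective is convex, an infeasible
#' unconstrained optimum projects onto the rank-one boundary `B^2 = A C`,
#' which is solved exactly through the parameterization
#' `sigma^2 k = (u + v z)^2`. Noise-free quadratic data are recovered
#' exactly.
#'
#' @param z Plane positions, beam coordinate in cm (>= 3 distinct values).
#' @param sigma Spot sigmas in cm at those planes.
#' @param convention Moment convention of the result.
#' @param enforce_constraint Require a nonnegative covariance determinant?
#' @param axis Axis label carried into the result.
#' @param z_ref Reference plane of the returned moments (beam coordinate).
#' @return List of class `fit_result`: `phase_space`, `residuals` (per plane,
#'   cm, on the sigma scale), `determinant`, `constraint_active`, `warnings`.
#' @export
fit_phase_space <- function(z, sigma,
                            convention = c("variance", "eclipse_cylindrical"),
                            enforce_constraint = TRUE, axis = "x",
                            z_ref = 0) {
  convention <- match.arg(convention)
  stopifnot(length(z) == length(sigma), all(sigma > 0))
  if (length(unique(z)) < 3) {
    if (length(unique(z)) == 1 && length(z) >= 1)
      stop("degenerate design: all planes at the same position")
    stop("underdetermined: need at least 3 distinct planes")
  }
  k <- if (convention == "eclipse_cylindrical") 2 else 1
  zz <- z - z_ref
  y <- k * sigma^2
  fit <- stats::lm(y ~ zz + I(zz^2))
  co <- stats::coef(fit)
  A <- unname(co[1]); B <- unname(co[2]) / 2; C <- unname(co[3])
  warnings <- character(0)
  constraint_active <- FALSE
  det_unc <- A * C - B^2
  if (enforce_constraint && (det_unc < 0 || A < 0 || C < 0)) {
    constraint_active <- TRUE
    warnings <- c(warnings, sprintf(
      "unconstrained optimum infeasible (determinant %.4g); projected onto the determinant-zero boundary",
      det_unc))
    obj <- function(p) sum((y - (p[1] + p[2] * zz)^2)^2)
    grad <- function(p) {
      r <- y - (p[1] + p[2] * zz)^2
      c(-4 * sum(r * (p[1] + p[2] * zz)),
        -4 * sum(r * (p[1] + p[2] * zz) * zz))
    }
    starts <- list(c(sqrt(max(A, mean(y))), sqrt(max(C, 0))),
                   c(sqrt(max(A, mean(y))), -sqrt(max(C, 0))),
                   c(sqrt(mean(y)), 0))
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    u <- best$par[1]; v <- best$par[2]
    A <- u^2; B <- u * v; C <- v^2
  }
  A <- max(A, 0); C <- max(C, 0)
  ps <- phase_space(A, B, C, z_ref = z_ref, axis = axis,
                    convention = convention)
  pred <- sqrt(pmax(C * zz^2 + 2 * B * zz + A, 0) / k)
  structure(list(phase_space = ps,
                 residuals = sigma - pred,
                 determinant = A * C - B^2,
                 constraint_active = constraint_active,
                 warnings = warnings),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  print(x$phase_space)
  cat(sprintf("  determinant %.4g, constraint %s, rms residual %.3g cm\n",
              x$determinant,
              if (x$constraint_active) "ACTIVE" else "inactive",
              sqrt(mean(x$residuals^2))))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Fit one slice of a spot dataset
#'
#' Selects the rows of a [make_lynx_dataset()]-style dataset for one energy,
#' axis and range-shifter state, converts measurement units (mm, isocenter
#' coordinates) to the internal convention and fits [fit_phase_space()].
#'
#' @param dataset A `spot_dataset` data.frame.
#' @param energy Energy in MeV.
#' @param axis `"x"` or `"y"`.
#' @param rs_in Logical: with (`TRUE`) or without the range shifter.
#' @param ... Passed to [fit_phase_space()].
#' @return A `fit_result`.
#' @export
fit_spot_slice <- function(dataset, energy, axis, rs_in, ...) {
  rows <- dataset[abs(dataset$energy_MeV - energy) < 1e-9 &
                    dataset$axis == axis & dataset$rs_in == rs_in, ]
  if (nrow(rows) == 0)
    stop("no rows for energy ", energy, " MeV, axis ", axis,
         ", rs_in = ", rs_in)
  fit_phase_space(z = iso_to_beam(rows$z_cm), sigma = rows$sigma_mm / 10,
                  axis = axis, ...)
}

#' Commission the V-parameter model from a spot dataset
#'
#' Fits per-energy, per-axis phase spaces from the open-beam and
#' with-RS-at-reference measurements, extracts the three per-equation V
#' estimates for each, and averages. The default follows the TPS behavior of
#' averaging over the three equations and all commissioning energies (axes
#' pooled); the per-energy table is always retained, and predictions may use
#' it instead (`v_mode = "per_energy"` in [run_comparison()]), which is the
#' configuration that tracks the reference methods most closely.
#'
#' @param dataset A `spot_dataset` containing open-beam rows and with-RS rows
#'   at the commissioning face position.
#' @param vm_template A [vmodel()] with `L_wet` and `S_reference` set.
#' @param energies Energies to commission (default: all in the dataset).
#' @param pool_axes Extract V from both axes and pool them?
#' @param convention Moment convention for the fits.
#' @return List of class `commissioning`: `v_average`, `v_table`
#'   (per energy/axis estimates), `v_per_energy`, `fits` (open and RS
#'   `fit_result`s), `vm` (template with `V = v_average`), `warnings`.
#' @export
commission_vmodel <- function(dataset, vm_template, energies = NULL,
                              pool_axes = TRUE,
                              convention = c("variance", "eclipse_cylindrical")) {
  convention <- match.arg(convention)
  rs_rows <- dataset$rs_in &
    abs(dataset$rs_face_cm - vm_template$S_reference) < 1e-9
  if (!any(rs_rows))
    stop("configuration error: no with-RS rows at the commissioning face position ",
         vm_template$S_reference, " cm")
  if (!any(!dataset$rs_in))
    stop("configuration error: no open-beam rows in the commissioning dataset")
  if (is.null(energies))
    energies <- sort(unique(dataset$energy_MeV[rs_rows]))
  axes <- if (pool_axes) c("x", "y") else "x"
  fits <- list(); rows <- list(); warns <- character(0)
  for (E in energies) for (ax in axes) {
    f_open <- fit_spot_slice(dataset, E, ax, rs_in = FALSE,
                             convention = convention)
    f_rs <- fit_spot_slice(dataset, E, ax, rs_in = TRUE,
                           convention = convention)
    warns <- c(warns, f_open$warnings, f_rs$warnings)
    est <- extract_v(f_open$phase_space, f_rs$phase_space, vm_template, E)
    key <- sprintf("E%g_%s", E, ax)
    fits[[key]] <- list(open = f_open, rs = f_rs, v = est)
    rows[[key]] <- data.frame(energy_MeV = E, axis = ax,
                              V_A = est$per_equation[["A"]],
                              V_B = est$per_equation[["B"]],
                              V_C = est$per_equation[["C"]],
                              V_mean = est$mean)
  }
  v_table <- do.call(rbind, rows)
  rownames(v_table) <- NULL
  v_per_energy <- stats::aggregate(V_mean ~ energy_MeV, v_table, mean)
  v_average <- mean(c(v_table$V_A, v_table$V_B, v_table$V_C))
  vm <- vm_template
  vm$V <- v_average
  structure(list(v_average = v_average, v_table = v_table,
                 v_per_energy = v_per_energy, fits = fits, vm = vm,
                 convention = convention, warnings = unique(warns)),
            class = "commissioning")
}

#' @export
print.commissioning <- function(x, ...) {
  cat(sprintf("<commissioning> V = %.5g (averaged over %d equation estimates)\n",
              x$v_average, 3L * nrow(x$v_table)))
  print(x$v_per_energy, row.names = FALSE)
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Write a commissioning report
#'
#' JSON report with per-energy open/with-RS moments, per-equation V values,
#' the average V, and accumulated warnings.
#'
#' @param comm A [commission_vmodel()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_commissioning_report <- function(comm, path) {
  per_energy <- lapply(comm$fits, function(f) {
    list(energy_MeV = f$v$E,
         axis = f$open$phase_space$axis,
         open = f$open$phase_space[c("A", "B", "C")],
         with_rs = f$rs$phase_space[c("A", "B", "C")],
         determinant_open = f$open$determinant,
         constraint_active_open = f$open$constraint_active,
         V = as.list(f$v$per_equation))
  })
  jsonlite::write_json(
    list(convention = comm$convention,
         L_wet_cm = comm$vm$L_wet, S_reference_cm = comm$vm$S_reference,
         V_average = comm$v_average,
         per_energy = per_energy,
         warnings = comm$warnings),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Emulate the high-energy parameter clamp defect
#'
#' Reproduces the planning-system flaw that froze the phase-space parameters
#' of all energies whose in-air spot sigma at isocenter fell below a
#' threshold (about 3.8 mm): affected rows are replaced by the values of the
#' highest unaffected energy (constant continuation) and flagged; lower
#' energies are untouched.
#'
#' @param table data.frame with columns `energy_MeV`, `A`, `B`, `C`, sorted
#'   by increasing energy, moments referenced at isocenter.
#' @param sigma_threshold Threshold in cm (default 0.38 cm = 3.8 mm). Zero
#'   disables the clamp.
#' @param convention Convention of the stored moments (`A = 2 sigma_iso^2`
#'   under `eclipse_cylindrical`).
#' @return The table with `A`, `B`, `C` possibly overwritten and a logical
#'   `clamped` column.
#' @export
emulate_parameter_clamp <- function(table, sigma_threshold = 0.38,
                                    convention = c("variance", "eclipse_cylindrical")) {
  convention <- match.arg(convention)
  stopifnot(all(c("energy_MeV", "A", "B", "C") %in% names(table)))
  if (is.unsorted(table$energy_MeV))
    stop("table must be sorted by increasing energy")
  k <- if (convention == "eclipse_cylindrical") 2 else 1
  sig_iso <- sqrt(table$A / k)
  table$clamped <- sig_iso < sigma_threshold
  if (any(table$clamped)) {
    donors <- which(!table$clamped)
    for (i in which(table$clamped)) {
      donor <- donors[donors < i]
      if (length(donor) == 0) next   # no lower unaffected energy to copy
      j <- max(donor)
      table[i, c("A", "B", "C")] <- table[j, c("A", "B", "C")]
    }
  }
  table
}

#' Check the validity of a with-RS envelope correction
#'
#' A scattering correction can only widen the beam downstream of the range
#' shifter, so `sigma_RS(z) >= sigma_open(z)` must hold on the patient side
#' of the RS face (`comparison_region = "downstream_only"`, the correct
#' check). The flawed planning-system comparison extended the corrected
#' envelope upstream of the RS face over the whole axis
#' (`comparison_region = "global"`); for a narrow-waist beam the
#' extrapolated corrected envelope can dip below the open envelope there,
#' which is the unphysical condition that triggered the spurious discard of
#' the correction.
#'
#' @param ps_open,ps_rs_corrected [phase_space()] objects at the same
#'   reference plane.
#' @param rs_downstream_face RS downstream face, cm from isocenter (positive
#'   toward the nozzle).
#' @param comparison_region `"downstream_only"` or `"global"`.
#' @param z_grid Evaluation grid, beam coordinate in cm.
#' @return List: `pass`, `region`, `violations` (data.frame of planes where
#'   the corrected envelope is below the open one, beam coordinates).
#' @export
check_rs_correction_validity <- function(ps_open, ps_rs_corrected,
                                         rs_downstream_face,
                                         comparison_region = c("downstream_only", "global"),
                                         z_grid = seq(-50, 50, by = 0.5)) {
  comparison_region <- match.arg(comparison_region)
  s_face <- iso_to_beam(rs_downstream_face)
  z <- if (comparison_region == "downstream_only")
    z_grid[z_grid >= s_face] else z_grid
  s_open <- sigma_at(ps_open, z)
  s_rs <- sigma_at(ps_rs_corrected, z)
  bad <- s_rs < s_open - 1e-12
  list(pass = !any(bad), region = comparison_region,
       violations = data.frame(z = z[bad], sigma_open = s_open[bad],
                               sigma_rs = s_rs[bad]))
}
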