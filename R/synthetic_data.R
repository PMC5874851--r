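## Synthetic spot-size datasets emulating scintillation-screen (Lynx-style)
## in-air measurements, plus the canonical scenario grid of the study: five
## energies (105, 140, 160, 225, 226.7 MeV), three range-shifter positions
## (17.5, 26.5, 36.5 cm), open beams, and a three-energy validation set.

#' Default truth phase-space table
#'
#' Per-energy, per-axis ground-truth moments for the synthetic dataset.
#' In-air spot sigma at isocenter descends from about 6 mm at 105 MeV to
#' about 3 mm at 226.7 MeV with a near-isocenter waist and a few mrad of
#' divergence, so that the 3.8 mm clamp threshold is crossed between 160 and
#' 225 MeV. These are fixture constants emulating a realistic
#' cyclotron-nozzle beam, not measured values; the y axis is made slightly
#' wider and more divergent than x so the axes are distinguishable.
#'
#' @param energies Energies in MeV.
#' @return data.frame with columns `energy_MeV`, `axis`, `A`, `B`, `C`
#'   (variance convention, referenced at isocenter, beam coordinates).
#' @export
default_truth_table <- function(energies = c(105, 120, 140, 160, 180, 225, 226.7)) {
  rows <- lapply(energies, function(E) {
    frac <- (E - 105) / (226.7 - 105)
    do.call(rbind, lapply(c("x", "y"), function(ax) {
      s_iso <- (6.0 - 3.0 * frac) / 10 * if (ax == "y") 1.05 else 1   # cm
      theta <- (4.0 - 1.5 * frac) / 1000 * if (ax == "y") 1.1 else 1  # rad
      z_w <- (-3 + 4 * frac) + if (ax == "y") 1.5 else 0              # cm, beam coord
      C <- theta^2
      sw2 <- s_iso^2 - C * z_w^2
      data.frame(energy_MeV = E, axis = ax,
                 A = C * z_w^2 + sw2, B = -C * z_w, C = C)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

truth_ps <- function(truth, E, ax, convention = "variance") {
  row <- truth[abs(truth$energy_MeV - E) < 1e-9 & truth$axis == ax, ]
  if (nrow(row) != 1) stop("truth table has no unique row for ", E, " MeV / ", ax)
  k <- if (convention == "eclipse_cylindrical") 2 else 1
  phase_space(k * row$A, k * row$B, k * row$C, z_ref = 0, axis = ax,
              convention = convention)
}

#' Generate a synthetic in-air spot-size dataset
#'
#' Computes sigma(z) at the requested planes from the truth phase spaces --
#' via [free_drift()] for the open beam or Fermi-Eyges slab moments
#' ([rs_fermi_eyges_moments()]) with the range shifter inserted -- and adds
#' i.i.d. Gaussian measurement noise. With `noise_sd = 0` the dataset carries
#' exact model values and phase-space fits recover the truth exactly.
#'
#' @param truth Truth table as from [default_truth_table()].
#' @param rs An [rs_setup()] (its `downstream_face_position` is used), or
#'   `NULL` for the open beam.
#' @param planes Measurement planes, cm from isocenter (positive toward the
#'   nozzle); default the scintillation-screen grid -20 ... +20 in 10 cm
#'   steps.
#' @param noise_sd Measurement noise standard deviation in mm.
#' @param seed Seed for the noise draw.
#' @param energies Subset of truth energies (default: all).
#' @return A `spot_dataset` data.frame with columns `energy_MeV`, `axis`,
#'   `z_cm`, `sigma_mm`, `sigma_err_mm`, `rs_in`, `rs_face_cm`, and a
#'   `provenance` attribute sufficient to regenerate it.
#' @export
make_lynx_dataset <- function(truth = default_truth_table(), rs = NULL,
                              planes = seq(-20, 20, by = 10),
                              noise_sd = 0.05, seed = NULL,
                              energies = unique(truth$energy_MeV)) {
  stopifnot(length(planes) >= 3, noise_sd >= 0)
  grid <- expand.grid(energy_MeV = energies, axis = c("x", "y"),
                      stringsAsFactors = FALSE)
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(i) {
      E <- grid$energy_MeV[i]; ax <- grid$axis[i]
      ps <- truth_ps(truth, E, ax)
      if (!is.null(rs)) {
        mom <- rs_fermi_eyges_moments(E, rs, S = rs$downstream_face_position)
        ps <- transport_with_scattering(ps, mom)
      }
      sig_mm <- 10 * sigma_at(ps, iso_to_beam(planes))
      if (noise_sd > 0) sig_mm <- sig_mm + stats::rnorm(length(planes), 0, noise_sd)
      data.frame(energy_MeV = E, axis = ax, z_cm = planes,
                 sigma_mm = sig_mm,
                 sigma_err_mm = max(noise_sd, 1e-3),
                 rs_in = !is.null(rs),
                 rs_face_cm = if (is.null(rs)) NA_real_ else rs$downstream_face_position)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$sigma_mm <= 0)) stop("noise drove a sigma nonpositive; reduce noise_sd")
  class(out) <- c("spot_dataset", "data.frame")
  attr(out, "provenance") <- list(
    truth = truth[truth$energy_MeV %in% energies, ],
    noise_sd_mm = noise_sd, seed = seed,
    rs = if (is.null(rs)) NULL else
      list(material = rs$material$name,
           physical_thickness_cm = rs$physical_thickness,
           wet_cm = rs$wet,
           downstream_face_cm = rs$downstream_face_position),
    planes_cm = planes)
  out
}

#' Combine spot datasets
#'
#' Row-binds `spot_dataset` objects (e.g. open-beam and with-RS halves of a
#' commissioning set), concatenating their provenance blocks.
#'
#' @param ... `spot_dataset` objects.
#' @return A `spot_dataset`.
#' @export
bind_spot_datasets <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("spot_dataset", "data.frame")
  attr(out, "provenance") <- lapply(parts, attr, "provenance")
  out
}

#' The study's scenario grid
#'
#' The full factorial of the five study energies and three range-shifter
#' downstream-face positions, the five open-beam runs, and the three-energy
#' validation set measured with the shifter at the commissioning position.
#' The commissioning flag marks the with-RS scenarios at 36.5 cm.
#'
#' @return data.frame with columns `scenario`, `role` (`"with_rs"`,
#'   `"open"`, `"validation_rs"`, `"validation_open"`), `energy_MeV`,
#'   `rs_face_cm` (`NA` for open beams), `commissioning`.
#' @export
paper_scenarios <- function() {
  energies <- c(105, 140, 160, 225, 226.7)
  faces <- c(17.5, 26.5, 36.5)
  grid <- expand.grid(energy_MeV = energies, rs_face_cm = faces)
  main <- data.frame(
    scenario = sprintf("E%g_RS%g", grid$energy_MeV, grid$rs_face_cm),
    role = "with_rs", energy_MeV = grid$energy_MeV,
    rs_face_cm = grid$rs_face_cm,
    commissioning = grid$rs_face_cm == 36.5)
  open <- data.frame(
    scenario = sprintf("E%g_open", energies),
    role = "open", energy_MeV = energies, rs_face_cm = NA_real_,
    commissioning = FALSE)
  val_e <- c(120, 180, 226.7)
  val <- rbind(
    data.frame(scenario = sprintf("E%g_RS36.5_val", val_e),
               role = "validation_rs", energy_MeV = val_e,
               rs_face_cm = 36.5, commissioning = FALSE),
    data.frame(scenario = sprintf("E%g_open_val", val_e),
               role = "validation_open", energy_MeV = val_e,
               rs_face_cm = NA_real_, commissioning = FALSE))
  rbind(main, open, val)
}

#' Write / read a spot dataset
#'
#' CSV with the dataset schema plus a JSON provenance sidecar
#' (`<path>.provenance.json`).
#'
#' @param dataset A `spot_dataset`.
#' @param path CSV file path.
#' @return `path` (write) or the `spot_dataset` (read).
#' @export
write_spot_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  prov <- attr(dataset, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_spot_dataset
#' @export
read_spot_dataset <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("spot_dataset", "data.frame")
  side <- paste0(path, ".provenance.json")
  if (file.exists(side))
    attr(out, "provenance") <- jsonlite::read_json(side, simplifyVector = TRUE)
  out
}
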