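## The evaluation pipeline: commission the V-parameter model from a
## synthetic dataset, then confront three methods -- Fermi-Eyges analytics,
## Monte Carlo, and the V-parameter model -- across scenarios, and render
## tables, summaries and envelope plots.

#' Run the three-method comparison
#'
#' Commissions the V-parameter model from the supplied dataset (open beam
#' plus range shifter at the commissioning position), then for every
#' scenario evaluates spot sigma at the standard planes with (1) the
#' Fermi-Eyges slab integrals, (2) the condensed-history Monte Carlo, and
#' (3) the V-parameter prediction, and tabulates their differences.
#' Relative differences use the Fermi-Eyges value as denominator.
#'
#' @param scenarios Scenario table as from [paper_scenarios()].
#' @param commissioning A `spot_dataset` holding open-beam rows and with-RS
#'   rows at the commissioning face position for every scenario energy.
#' @param rs_template [rs_setup()] describing the slab; its face position is
#'   overridden per scenario.
#' @param planes Evaluation planes, cm from isocenter.
#' @param n_protons Monte Carlo protons per scenario (0 disables MC).
#' @param seed Base seed; per-scenario seeds are derived deterministically.
#' @param step Monte Carlo step inside the slab, cm.
#' @param v_mode `"per_energy"` (each energy predicted with its own
#'   equation-averaged V; tracks the references most closely) or
#'   `"average"` (single V pooled over equations and energies, the TPS
#'   behavior).
#' @param emulate_clamp Apply the high-energy parameter-clamp defect to the
#'   phase spaces used by the V-parameter route?
#' @param clamp_threshold Clamp threshold in cm (default 0.38 = 3.8 mm).
#' @return A `comparison_table` data.frame; the commissioning object, the
#'   options and any warnings ride along as attributes.
#' @export
run_comparison <- function(scenarios = paper_scenarios(),
                           commissioning,
                           rs_template,
                           planes = seq(-20, 20, by = 5),
                           n_protons = 200000, seed = 1, step = 0.1,
                           v_mode = c("per_energy", "average"),
                           emulate_clamp = FALSE, clamp_threshold = 0.38) {
  v_mode <- match.arg(v_mode)
  stopifnot(inherits(rs_template, "rs_setup"))
  vm_template <- vmodel(L_wet = rs_template$wet, S_reference = 36.5)
  comm <- commission_vmodel(commissioning, vm_template)
  need <- unique(scenarios$energy_MeV)
  have <- unique(comm$v_per_energy$energy_MeV)
  missing_e <- setdiff(need, have)
  if (length(missing_e) > 0)
    stop("configuration error: commissioning dataset lacks energies ",
         paste(missing_e, collapse = ", "), " MeV")
  warnings <- comm$warnings

  open_ps <- function(E, ax) comm$fits[[sprintf("E%g_%s", E, ax)]]$open$phase_space
  ## TPS-side (possibly clamped) open tables, one per axis
  tps_tab <- lapply(c(x = "x", y = "y"), function(ax) {
    tab <- do.call(rbind, lapply(sort(have), function(E) {
      ps <- open_ps(E, ax)
      data.frame(energy_MeV = E, A = ps$A, B = ps$B, C = ps$C)
    }))
    if (emulate_clamp) {
      tab <- emulate_parameter_clamp(tab, sigma_threshold = clamp_threshold,
                                     convention = comm$convention)
    } else tab$clamped <- FALSE
    tab
  })
  tps_ps <- function(E, ax) {
    row <- tps_tab[[ax]][abs(tps_tab[[ax]]$energy_MeV - E) < 1e-9, ]
    list(ps = phase_space(row$A, row$B, row$C, z_ref = 0, axis = ax,
                          convention = comm$convention),
         clamped = row$clamped)
  }
  v_for <- function(E) {
    if (v_mode == "average") comm$v_average
    else comm$v_per_energy$V_mean[abs(comm$v_per_energy$energy_MeV - E) < 1e-9]
  }

  z_beam <- iso_to_beam(planes)
  out <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    E <- sc$energy_MeV
    has_rs <- !is.na(sc$rs_face_cm)
    rs_i <- if (has_rs) {
      rs_setup(rs_template$material, rs_template$physical_thickness,
               downstream_face_position = sc$rs_face_cm, wet = rs_template$wet)
    } else NULL
    vm_i <- comm$vm
    vm_i$V <- v_for(E)
    for (ax in c("x", "y")) {
      ps0 <- open_ps(E, ax)
      tps <- tps_ps(E, ax)
      ## Fermi-Eyges reference (piecewise: physical at every plane, also
      ## inside and upstream of the slab)
      sig_fe <- 10 * fe_sigma_envelope(ps0, E, rs_i, z_beam)
      ## V-parameter route (from the TPS-side table)
      ps_v <- if (has_rs) {
        predict_with_rs(tps$ps, vm_i, E, L = vm_i$L_wet, S = sc$rs_face_cm)
      } else tps$ps
      sig_v <- 10 * sigma_at(ps_v, z_beam)
      ## Monte Carlo
      if (n_protons > 0) {
        src_x <- free_drift(open_ps(E, "x"), -50)
        src_y <- free_drift(open_ps(E, "y"), -50)
        sc_seed <- as.integer(seed) + 101L * i
        bundle <- sample_source(src_x, src_y, n = n_protons,
                                seed = sc_seed, energy = E)
        tallies <- transport(bundle, rs = rs_i, tally_positions = z_beam,
                             step = step, seed = sc_seed + 50L)
        mc <- do.call(rbind, lapply(tallies, tally_sigma))
        mc_ax <- mc[mc$axis == ax, ]
        sig_mc <- 10 * mc_ax$sigma_cm
        se_mc <- 10 * mc_ax$se_cm
      } else {
        sig_mc <- rep(NA_real_, length(planes))
        se_mc <- rep(NA_real_, length(planes))
      }
      out[[length(out) + 1]] <- data.frame(
        scenario = sc$scenario, role = sc$role, energy_MeV = E,
        rs_face_cm = sc$rs_face_cm, axis = ax, z_cm = planes,
        sigma_fe_mm = sig_fe, sigma_mc_mm = sig_mc, sigma_mc_se_mm = se_mc,
        sigma_v_mm = sig_v,
        diff_mc_fe_mm = sig_mc - sig_fe,
        diff_v_fe_mm = sig_v - sig_fe,
        rel_v_fe_pct = 100 * (sig_v - sig_fe) / sig_fe,
        clamped = tps$clamped)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("comparison_table", "data.frame")
  attr(tab, "commissioning") <- comm
  attr(tab, "options") <- list(n_protons = n_protons, seed = seed,
                               step = step, v_mode = v_mode,
                               emulate_clamp = emulate_clamp,
                               clamp_threshold = clamp_threshold)
  attr(tab, "warnings") <- warnings
  tab
}

summarize_comparison <- function(table) {
  per <- lapply(split(as.data.frame(table), table$scenario), function(d) {
    list(scenario = d$scenario[1], role = d$role[1],
         energy_MeV = d$energy_MeV[1],
         rs_face_cm = if (is.na(d$rs_face_cm[1])) NULL else d$rs_face_cm[1],
         max_abs_diff_v_fe_mm = max(abs(d$diff_v_fe_mm)),
         mean_abs_diff_v_fe_mm = mean(abs(d$diff_v_fe_mm)),
         max_abs_rel_v_fe_pct = max(abs(d$rel_v_fe_pct)),
         max_abs_diff_mc_fe_mm = if (all(is.na(d$diff_mc_fe_mm))) NULL else
           max(abs(d$diff_mc_fe_mm)),
         clamped = any(d$clamped))
  })
  names(per) <- NULL
  list(per_scenario = per,
       max_abs_rel_v_fe_pct = max(abs(table$rel_v_fe_pct)),
       max_abs_diff_mc_fe_mm = if (all(is.na(table$diff_mc_fe_mm))) NULL else
         max(abs(table$diff_mc_fe_mm), na.rm = TRUE),
       warnings = as.list(attr(table, "warnings")))
}

#' Render a comparison report
#'
#' Writes the comparison table as CSV, a JSON summary (per-scenario maximum
#' and mean differences, warnings, and the full table for round-tripping),
#' and per-scenario sigma(z) envelope plots.
#'
#' @param table A [run_comparison()] result.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json", "plots")`.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(table, dir, formats = c("csv", "json", "plots")) {
  stopifnot(nrow(table) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  if ("csv" %in% formats) {
    f <- file.path(dir, "comparison.csv")
    utils::write.csv(as.data.frame(table), f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(c(summarize_comparison(table),
                           list(table = as.data.frame(table))),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    files <- c(files, f)
  }
  if ("plots" %in% formats) {
    for (sc in unique(table$scenario)) {
      d <- as.data.frame(table[table$scenario == sc, ])
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z_cm)) +
        ggplot2::geom_line(ggplot2::aes(y = .data$sigma_fe_mm,
                                        colour = "Fermi-Eyges")) +
        ggplot2::geom_point(ggplot2::aes(y = .data$sigma_mc_mm,
                                         colour = "Monte Carlo"), shape = 1) +
        ggplot2::geom_point(ggplot2::aes(y = .data$sigma_v_mm,
                                         colour = "V model"), shape = 4) +
        ggplot2::facet_wrap(~axis) +
        ggplot2::labs(x = "plane position from isocenter (cm)",
                      y = "spot sigma (mm)",
                      colour = NULL, title = sc) +
        ggplot2::theme_minimal()
      f <- file.path(dir, paste0("envelope_", gsub("[^A-Za-z0-9_.-]", "_", sc), ".png"))
      grDevices::png(f, width = 900, height = 450, res = 110)
      print(p)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read back a JSON comparison summary
#'
#' @param path `summary.json` written by [render_report()].
#' @return List with the summary fields; `$table` is the comparison table as
#'   a data.frame.
#' @export
read_comparison_summary <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$table <- as.data.frame(out$table)
  out
}
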