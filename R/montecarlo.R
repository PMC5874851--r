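## Desk-scale condensed-history Monte Carlo pencil-beam transport: Gaussian
## source sampling, straight drifts in air, per-step correlated
## position/angle kicks inside the range-shifter slab, fluence tallies, and
## Gaussian profile extraction. Gaussian-core physics only (no nuclear
## interactions, no secondaries, no straggling), matching the benchmark
## simplifications.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Sample a Gaussian pencil-beam source
#'
#' Draws `(x, theta_x)` and `(y, theta_y)` independently per axis from the
#' zero-mean bivariate Gaussian with covariance `[[A, B], [B, C]]` (on the
#' variance scale of the stored convention). Both phase spaces must be
#' referenced at the same source plane, typically back-projected upstream of
#' the range shifter with [free_drift()].
#'
#' @param ps_x,ps_y [phase_space()] objects for the two axes at the same
#'   `z_ref`.
#' @param n Number of protons.
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @param energy Kinetic energy in MeV shared by the bundle.
#' @return Object of class `particle_bundle` with fields `x`, `y`,
#'   `theta_x`, `theta_y` (cm, rad), `energy`, `alive`, `n`, `seed`, `z_ref`.
#' @export
sample_source <- function(ps_x, ps_y, n, seed = NULL, energy) {
  stopifnot(inherits(ps_x, "phase_space"), inherits(ps_y, "phase_space"),
            n >= 1, energy > 0)
  if (abs(ps_x$z_ref - ps_y$z_ref) > 1e-9)
    stop("source phase spaces must share the reference plane")
  draw_axis <- function(ps) {
    k <- conv_factor(ps)
    A <- ps$A / k; B <- ps$B / k; C <- ps$C / k
    if (A == 0 && C == 0) return(list(x = numeric(n), th = numeric(n)))
    det <- A * C - B^2
    if (det <= 0)
      stop("nonphysical source: emittance ", det,
           " <= 0, covariance cannot be factored")
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    x <- sqrt(A) * z1
    th <- B / sqrt(A) * z1 + sqrt(det / A) * z2
    list(x = x, th = th)
  }
  with_seed(seed, {
    ax <- draw_axis(ps_x)
    ay <- draw_axis(ps_y)
    structure(list(x = ax$x, y = ay$x, theta_x = ax$th, theta_y = ay$th,
                   energy = energy, alive = rep(TRUE, n), n = n,
                   seed = seed, z_ref = ps_x$z_ref),
              class = "particle_bundle")
  })
}

#' @export
print.particle_bundle <- function(x, ...) {
  cat(sprintf("<particle_bundle> n = %d at z = %g cm, E = %g MeV (seed %s)\n",
              x$n, x$z_ref, x$energy,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

## one condensed-history slab traversal; mutates (x, theta) per axis.
## Step kicks use the exact within-step Fermi-Eyges moments
## (theta_s^2 h^2/3, theta_s^2 h/2, theta_s^2) at the step-midpoint pv, so
## the accumulated second moments are second-order accurate in step size.
## `checkpoints` are interior depths (cm from the upstream face) at which a
## snapshot of the bundle is taken (for tally planes inside the slab); the
## stepping is partitioned so each checkpoint falls on a step boundary.
slab_steps <- function(bundle, rs, step, log_correction,
                       checkpoints = numeric(0)) {
  m <- rs$material
  t <- rs$physical_thickness
  if (range_of_energy(bundle$energy, m) <= t)
    stop("all protons stopped inside the range shifter (E = ",
         bundle$energy, " MeV)")
  full_fac <- if (log_correction)
    1 + log10(m$density * t / m$radiation_length_mass) / 9 else 1
  E_in <- bundle$energy
  bounds <- sort(unique(c(0, checkpoints, t)))
  snapshots <- list()
  for (seg in seq_len(length(bounds) - 1)) {
    len <- bounds[seg + 1] - bounds[seg]
    n_steps <- max(1L, ceiling(len / step))
    h <- len / n_steps
    for (j in seq_len(n_steps)) {
      d_mid <- bounds[seg] + (j - 0.5) * h
      pv <- kinematic_factor(energy_at_depth(E_in, d_mid, m))
      th_s <- full_fac * 14.1 / pv * sqrt(m$density * h / m$radiation_length_mass)
      for (ax in c("x", "y")) {
        th_name <- paste0("theta_", ax)
        z1 <- stats::rnorm(bundle$n); z2 <- stats::rnorm(bundle$n)
        d_th <- th_s * z1
        d_x <- th_s * h * (z1 / 2 + z2 / sqrt(12))
        bundle[[ax]] <- bundle[[ax]] + bundle[[th_name]] * h + d_x
        bundle[[th_name]] <- bundle[[th_name]] + d_th
      }
    }
    d_here <- bounds[seg + 1]
    if (d_here %in% checkpoints) {
      snapshots[[as.character(d_here)]] <-
        list(x = bundle$x, y = bundle$y, depth = d_here)
    }
  }
  bundle$energy <- energy_at_depth(E_in, t, m)
  bundle$z_ref <- bundle$z_ref + t
  attr(bundle, "snapshots") <- snapshots
  bundle
}

drift_bundle <- function(bundle, dz) {
  bundle$x <- bundle$x + bundle$theta_x * dz
  bundle$y <- bundle$y + bundle$theta_y * dz
  bundle$z_ref <- bundle$z_ref + dz
  bundle
}

tally_at <- function(bundle, z) {
  dz <- z - bundle$z_ref
  structure(list(position = z,
                 x = bundle$x + bundle$theta_x * dz,
                 y = bundle$y + bundle$theta_y * dz,
                 n = bundle$n),
            class = "tally_plane")
}

#' @export
print.tally_plane <- function(x, ...) {
  cat(sprintf("<tally_plane z = %g cm> n = %d, sigma_x = %.3f mm, sigma_y = %.3f mm\n",
              x$position, x$n, 10 * stats::sd(x$x), 10 * stats::sd(x$y)))
  invisible(x)
}

#' Tallied spot sigma and its standard error
#'
#' Sample standard deviation of the tallied crossing positions per axis,
#' with the large-n standard error `sigma / sqrt(2 n)`.
#'
#' @param plane A `tally_plane`.
#' @return data.frame with `axis`, `sigma_cm`, `se_cm`, `n`.
#' @export
tally_sigma <- function(plane) {
  s <- c(x = stats::sd(plane$x), y = stats::sd(plane$y))
  data.frame(axis = names(s), sigma_cm = unname(s),
             se_cm = unname(s) / sqrt(2 * plane$n), n = plane$n)
}

#' Transport a particle bundle through air and an optional range shifter
#'
#' Drift segments are straight-line propagation; inside the slab, each step
#' applies a correlated position/angle kick with the exact within-step
#' Fermi-Eyges moments at the Highland step width (logarithmic factor
#' excluded per step by default; optionally reinstated once for the full
#' slab). Energy follows the Bragg-Kleeman slowing-down. Tally planes record
#' the crossing positions of every proton.
#'
#' @param bundle A [sample_source()] bundle.
#' @param rs An [rs_setup()], or `NULL` for open beam. The slab occupies
#'   `[face - t, face]` in beam coordinates where
#'   `face = iso_to_beam(rs$downstream_face_position)`.
#' @param tally_positions Tally planes, beam coordinates in cm, all
#'   downstream of the source; planes inside the slab are snapshotted at the
#'   matching depth during the stepping.
#' @param step Step length inside the slab, cm (default 0.1 cm = 1 mm).
#' @param seed Seed for the scattering RNG.
#' @param log_correction Reinstate the full-slab Highland log factor?
#' @return List of `tally_plane` objects, one per requested position (input
#'   order preserved).
#' @export
transport <- function(bundle, rs = NULL, tally_positions, step = 0.1,
                      seed = NULL, log_correction = FALSE) {
  stopifnot(inherits(bundle, "particle_bundle"))
  if (any(tally_positions < bundle$z_ref))
    stop("tally planes must be downstream of the source")
  order_idx <- order(tally_positions)
  zs <- tally_positions[order_idx]
  tallies <- vector("list", length(zs))
  if (is.null(rs)) {
    for (i in seq_along(zs)) tallies[[i]] <- tally_at(bundle, zs[i])
  } else {
    stopifnot(inherits(rs, "rs_setup"))
    s_face <- iso_to_beam(rs$downstream_face_position)
    s_up <- s_face - rs$physical_thickness
    if (bundle$z_ref > s_up)
      stop("source must be upstream of the range shifter")
    pre <- which(zs <= s_up)
    for (i in pre) tallies[[i]] <- tally_at(bundle, zs[i])
    interior <- which(zs > s_up & zs < s_face)
    bundle <- drift_bundle(bundle, s_up - bundle$z_ref)
    bundle <- with_seed(seed, slab_steps(bundle, rs, step, log_correction,
                                         checkpoints = zs[interior] - s_up))
    snaps <- attr(bundle, "snapshots")
    for (i in interior) {
      sn <- snaps[[as.character(zs[i] - s_up)]]
      tallies[[i]] <- structure(list(position = zs[i], x = sn$x, y = sn$y,
                                     n = bundle$n),
                                class = "tally_plane")
    }
    post <- which(zs >= s_face)
    for (i in post) tallies[[i]] <- tally_at(bundle, zs[i])
  }
  tallies[order(order_idx)]
}

## ---- profile fitting -----------------------------------------------------

fit_gauss_binned <- function(counts, edges) {
  stopifnot(length(edges) == length(counts) + 1)
  n <- sum(counts)
  if (n < 100) stop("need at least 100 counts for a profile fit")
  if (sum(counts > 0) < 2)
    stop("degenerate profile: all counts in a single bin")
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mu0 <- sum(counts * mids) / n
  s0 <- sqrt(sum(counts * (mids - mu0)^2) / n)
  nll <- function(p) {
    mu <- p[1]; s <- exp(p[2])
    pr <- pmax(stats::pnorm(edges[-1], mu, s) -
                 stats::pnorm(edges[-length(edges)], mu, s), 1e-300)
    -sum(counts * log(pr))
  }
  o <- stats::optim(c(mu0, log(s0)), nll, method = "BFGS",
                    hessian = TRUE, control = list(reltol = 1e-12))
  s_hat <- exp(o$par[2])
  se <- tryCatch({
    v <- solve(o$hessian)[2, 2]
    s_hat * sqrt(max(v, 0))       # delta method, log-sigma parameterization
  }, error = function(e) NA_real_)
  structure(list(sigma = s_hat, center = o$par[1], se_sigma = se,
                 n = n, loglik = -o$value),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  if (!is.null(x$sigma_x)) {
    cat(sprintf("<profile_fit 2D> sigma_x = %.4f, sigma_y = %.4f (rmse %.3g)\n",
                x$sigma_x, x$sigma_y, x$rmse))
  } else {
    cat(sprintf("<profile_fit> sigma = %.4f +/- %.2g, center = %.4f (n = %d)\n",
                x$sigma, x$se_sigma, x$center, x$n))
  }
  invisible(x)
}

#' Extract spot sigma from a fluence profile or image
#'
#' One-dimensional tallies (or raw position vectors) are binned and fitted
#' by maximum likelihood to a Gaussian, unbiased to O(1/n); two-dimensional
#' images are fitted by least squares to an elliptical Gaussian with a flat
#' background, the procedure used on exported dose planes.
#'
#' @param x A `tally_plane`, a numeric vector of positions (cm), or a
#'   numeric matrix (image).
#' @param ... Method arguments: `axis` and `bin_width` (cm) for tallies;
#'   `bin_width` for vectors; `pixel_spacing` (cm) for matrices.
#' @return A `profile_fit`: 1D fits carry `sigma`, `center`, `se_sigma`;
#'   2D fits carry `sigma_x`, `sigma_y`, `center`, `rmse`.
#' @export
fit_profiles <- function(x, ...) UseMethod("fit_profiles")

#' @rdname fit_profiles
#' @export
fit_profiles.numeric <- function(x, bin_width = 0.05, ...) {
  rng <- range(x)
  edges <- seq(rng[1] - bin_width, rng[2] + bin_width, by = bin_width)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  fit_gauss_binned(counts, edges)
}

#' @rdname fit_profiles
#' @export
fit_profiles.tally_plane <- function(x, axis = c("x", "y"), bin_width = 0.05, ...) {
  axis <- match.arg(axis)
  fit_profiles(x[[axis]], bin_width = bin_width)
}

#' @rdname fit_profiles
#' @export
fit_profiles.matrix <- function(x, pixel_spacing = 0.039, ...) {
  if (nrow(x) < 3 || ncol(x) < 3 || max(x) <= min(x))
    stop("degenerate image")
  xs <- (seq_len(ncol(x)) - (ncol(x) + 1) / 2) * pixel_spacing
  ys <- (seq_len(nrow(x)) - (nrow(x) + 1) / 2) * pixel_spacing
  X <- matrix(xs, nrow(x), ncol(x), byrow = TRUE)
  Y <- matrix(ys, nrow(x), ncol(x))
  tot <- sum(x)
  x0 <- sum(X * x) / tot; y0 <- sum(Y * x) / tot
  sx0 <- sqrt(max(sum((X - x0)^2 * x) / tot, pixel_spacing^2 / 12))
  sy0 <- sqrt(max(sum((Y - y0)^2 * x) / tot, pixel_spacing^2 / 12))
  obj <- function(p) {
    mdl <- p[1] * exp(-(X - p[2])^2 / (2 * exp(2 * p[4])) -
                        (Y - p[3])^2 / (2 * exp(2 * p[5]))) + p[6]
    sum((x - mdl)^2)
  }
  o <- stats::optim(c(max(x), x0, y0, log(sx0), log(sy0), min(x)), obj,
                    method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-13))
  structure(list(sigma_x = exp(o$par[4]), sigma_y = exp(o$par[5]),
                 center = c(o$par[2], o$par[3]),
                 rmse = sqrt(o$value / length(x))),
            class = "profile_fit")
}
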