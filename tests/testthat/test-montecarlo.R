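test_that("source sampling reproduces the target covariance and is seeded", {
  ps_x <- phase_space(0.36, -2e-4, 1.6e-5)
  ps_y <- phase_space(0.40, 1e-4, 2.0e-5)
  n <- 200000
  b <- sample_source(ps_x, ps_y, n, seed = 123, energy = 160)
  ## each second moment within 5 standard errors: SE = moment sqrt(2/n)
  ## for variances, sqrt((A C + B^2)/n) for the covariance
  chk <- function(sample_mom, target, se) {
    expect_lt(abs(sample_mom - target), 5 * se + 1e-12)
  }
  chk(mean(b$x^2), ps_x$A, ps_x$A * sqrt(2 / n))
  chk(mean(b$theta_x^2), ps_x$C, ps_x$C * sqrt(2 / n))
  chk(mean(b$x * b$theta_x), ps_x$B, sqrt((ps_x$A * ps_x$C + ps_x$B^2) / n))
  chk(mean(b$y^2), ps_y$A, ps_y$A * sqrt(2 / n))
  chk(mean(b$y * b$theta_y), ps_y$B, sqrt((ps_y$A * ps_y$C + ps_y$B^2) / n))
  ## determinism
  b2 <- sample_source(ps_x, ps_y, n, seed = 123, energy = 160)
  expect_identical(b$x, b2$x)
  expect_identical(b$theta_y, b2$theta_y)
  ## degenerate and nonphysical sources
  cold <- phase_space(0, 0, 0)
  b0 <- sample_source(cold, cold, 100, seed = 1, energy = 160)
  expect_true(all(b0$x == 0) && all(b0$theta_x == 0))
  bad <- phase_space(0.01, -0.05, 0.2)
  expect_error(sample_source(bad, bad, 100, seed = 1, energy = 160),
               "nonphysical source")
})

test_that("open-beam transport matches the free-drift envelope", {
  ps_x <- phase_space(0.36, -2e-4, 1.6e-5)
  ps_y <- phase_space(0.40, 1e-4, 2.0e-5)
  src_x <- free_drift(ps_x, -50)
  src_y <- free_drift(ps_y, -50)
  n <- 200000
  b <- sample_source(src_x, src_y, n, seed = 5, energy = 160)
  zs <- iso_to_beam(seq(-20, 20, by = 5))
  tallies <- transport(b, rs = NULL, tally_positions = zs)
  for (i in seq_along(zs)) {
    ts <- tally_sigma(tallies[[i]])
    expect_lt(abs(ts$sigma_cm[ts$axis == "x"] - sigma_at(ps_x, zs[i])),
              3 * ts$se_cm[ts$axis == "x"])
    expect_lt(abs(ts$sigma_cm[ts$axis == "y"] - sigma_at(ps_y, zs[i])),
              3 * ts$se_cm[ts$axis == "y"])
  }
})

test_that("slab transport agrees with Fermi-Eyges and converges in step size", {
  ps_x <- phase_space(0.36, -2e-4, 1.6e-5)
  ps_y <- phase_space(0.40, 1e-4, 2.0e-5)
  rs <- rs_at(26.5)
  n <- 200000
  E <- 140
  b <- sample_source(free_drift(ps_x, -50), free_drift(ps_y, -50), n,
                     seed = 21, energy = E)
  zs <- iso_to_beam(c(-20, 0, 20))
  mom <- rs_fermi_eyges_moments(E, rs, S = 26.5)
  fe_x <- transport_with_scattering(ps_x, mom)
  tl <- transport(b, rs, tally_positions = zs, seed = 22)
  sig1 <- numeric(length(zs))
  for (i in seq_along(zs)) {
    ts <- tally_sigma(tl[[i]])
    sig1[i] <- ts$sigma_cm[ts$axis == "x"]
    expect_lt(abs(sig1[i] - sigma_at(fe_x, zs[i])),
              max(0.01, 3 * ts$se_cm[ts$axis == "x"]))
  }
  ## angular variance after the slab equals C_open + delta_C: recover C
  ## from the tallied envelope curvature (positions at three planes of the
  ## same bundle are strongly correlated, so the curvature is precise)
  sfit <- vapply(tl, function(t) stats::sd(t$x), numeric(1))
  fit <- fit_phase_space(zs, sfit)
  expect_lt(rel_err(fit$phase_space$C, fe_x$C), 0.05)
  ## halving the step changes the tallied sigma by less than one SE
  b3 <- sample_source(free_drift(ps_x, -50), free_drift(ps_y, -50), n,
                      seed = 31, energy = E)
  t_half <- transport(b3, rs, tally_positions = iso_to_beam(0), step = 0.05,
                      seed = 32)
  ts <- tally_sigma(t_half[[1]])
  expect_lt(abs(ts$sigma_cm[ts$axis == "x"] - sig1[2]),
            2 * ts$se_cm[ts$axis == "x"] * sqrt(2))
})

test_that("tally planes inside the slab match the partial-depth envelope", {
  ps <- phase_space(0.36, -2e-4, 1.6e-5)
  rs <- rs_at(17.5)                       # slab spans [17.5, 24] cm from iso
  E <- 160
  n <- 200000
  b <- sample_source(free_drift(ps, -50), free_drift(ps, -50), n,
                     seed = 61, energy = E)
  zs <- iso_to_beam(c(25, 20, 15))        # upstream, interior, downstream
  tl <- transport(b, rs, tally_positions = zs, seed = 62)
  fe <- fe_sigma_envelope(ps, E, rs, zs)
  for (i in seq_along(zs)) {
    ts <- tally_sigma(tl[[i]])
    expect_lt(abs(ts$sigma_cm[ts$axis == "x"] - fe[i]),
              max(0.01, 3 * ts$se_cm[ts$axis == "x"]))
  }
})

test_that("a vanishingly thin shifter reproduces the open beam", {
  ps <- phase_space(0.36, 0, 1.6e-5)
  b <- sample_source(free_drift(ps, -50), free_drift(ps, -50), 20000,
                     seed = 9, energy = 160)
  thin <- rs_setup(lexan(), 1e-9, 26.5, wet = 1.2e-9)
  t1 <- transport(b, thin, tally_positions = 0, seed = 10)
  t2 <- transport(b, NULL, tally_positions = 0)
  expect_equal(stats::sd(t1[[1]]$x), stats::sd(t2[[1]]$x), tolerance = 1e-6)
})

test_that("transport rejects impossible geometries and stopped beams", {
  ps <- phase_space(0.36, 0, 1.6e-5)
  b <- sample_source(free_drift(ps, -50), free_drift(ps, -50), 1000,
                     seed = 2, energy = 160)
  expect_error(transport(b, NULL, tally_positions = -60), "downstream")
  b_slow <- sample_source(free_drift(ps, -50), free_drift(ps, -50), 1000,
                          seed = 2, energy = 60)
  expect_error(transport(b_slow, rs_at(36.5), tally_positions = 0, seed = 3),
               "stopped")
})

test_that("1D profile fitting recovers sigma from binned counts", {
  set.seed(77)
  x <- stats::rnorm(200000, sd = 0.5)          # 5 mm
  fit <- fit_profiles(x, bin_width = 0.05)     # 0.5 mm bins
  expect_lt(rel_err(fit$sigma, 0.5), 0.005)
  expect_lt(abs(fit$center), 0.01)
  expect_error(fit_profiles(stats::rnorm(50)), "at least 100")
  expect_error(fit_profiles(rep(0.123, 1000)), "degenerate|finite|single")
})

test_that("tally-plane profile fits agree with the sample SD", {
  ps <- phase_space(0.25, 0, 1e-5)
  b <- sample_source(free_drift(ps, -50), free_drift(ps, -50), 200000,
                     seed = 55, energy = 160)
  t0 <- transport(b, NULL, tally_positions = 0)[[1]]
  fit <- fit_profiles(t0, axis = "x", bin_width = 0.05)
  expect_lt(rel_err(fit$sigma, stats::sd(t0$x)), 0.01)
})

test_that("2D image fitting is symmetric and discretization-stable", {
  px <- 0.039                                  # dose-plane resolution, cm
  half <- 64
  xs <- (seq_len(2 * half) - half - 0.5) * px
  img <- exp(-outer(xs^2, xs^2, "+") / (2 * 0.4^2))
  fit <- fit_profiles(img, pixel_spacing = px)
  expect_equal(fit$sigma_x, fit$sigma_y, tolerance = 1e-6)
  expect_lt(rel_err(fit$sigma_x, 0.4), 0.005)
  ## 2x downsampling leaves sigma stable within the discretization tolerance
  sub <- img[seq(1, nrow(img), 2), seq(1, ncol(img), 2)]
  fit2 <- fit_profiles(sub, pixel_spacing = 2 * px)
  expect_lt(rel_err(fit2$sigma_x, fit$sigma_x), 0.01)
  expect_error(fit_profiles(matrix(1, 10, 10)), "degenerate")
})
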