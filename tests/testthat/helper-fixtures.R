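## Shared fixtures: all built in code, nothing read from disk beyond the
## package's own materials registry.

lexan <- function() get_material("lexan")
water <- function() get_material("water")

rs_at <- function(face, wet = NULL, thickness = 6.5) {
  rs_setup(lexan(), thickness, downstream_face_position = face, wet = wet)
}

paper_energies <- function() c(105, 140, 160, 225, 226.7)

rel_err <- function(a, b) abs(a - b) / abs(b)

## noise-free commissioning dataset (open + RS at 36.5) on the dose-plane
## grid, computed once per session
commissioning_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- default_truth_table()
      rs <- rs_at(36.5)
      cache <<- list(
        truth = truth, rs = rs,
        dataset = bind_spot_datasets(
          make_lynx_dataset(truth, NULL, planes = seq(-20, 20, 5), noise_sd = 0),
          make_lynx_dataset(truth, rs, planes = seq(-20, 20, 5), noise_sd = 0)))
    }
    cache
  }
})

## brute-force trapezoid oracle for the five-thirds integrals, independent
## of the ODE implementation
five_thirds_oracle <- function(beta, beta_cut, n = 1e6) {
  b <- seq(beta_cut, beta, length.out = n)
  h <- b[2] - b[1]
  ctrap <- function(y) c(0, cumsum((y[-1] + y[-length(y)]) / 2)) * h
  f_phi <- b^(-4 / 3) * (1 - b^2)^(-4 / 3)
  wgt <- b^(-8 / 3) * (1 - b^2)^(-3 / 2)
  phi <- ctrap(f_phi)
  chi <- ctrap(phi * wgt)
  psi <- ctrap(chi * wgt)
  c(phi = phi[n], chi = chi[n], psi = psi[n])
}

## random physical phase space (positive emittance)
random_ps <- function(axis = "x") {
  A <- runif(1, 0.05, 0.5)
  C <- runif(1, 1e-6, 5e-5)
  B <- runif(1, -0.9, 0.9) * sqrt(A * C)
  phase_space(A, B, C, axis = axis)
}
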