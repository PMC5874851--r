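## The nested beta-integrals of the five-thirds stopping-power approximation
## used by the TPS-style V-parameter model. All three (and the weight
## antiderivative w used for the self-consistent material factor) are solved
## in one pass as an ODE system in beta, which handles the nesting without
## re-quadrature:
##   phi' = 1 / (b^(4/3) (1-b^2)^(4/3))
##   chi' = phi / (b^(8/3) (1-b^2)^(3/2))
##   psi' = chi / (b^(8/3) (1-b^2)^(3/2))
##   w'   =   1 / (b^(8/3) (1-b^2)^(3/2))

five_thirds_rhs <- function(b, y, parms) {
  f_phi <- b^(-4 / 3) * (1 - b^2)^(-4 / 3)
  wgt <- b^(-8 / 3) * (1 - b^2)^(-3 / 2)
  list(c(f_phi, y[1] * wgt, y[2] * wgt, wgt))
}

#' Five-thirds approximation integrals
#'
#' The cumulative integrals entering the V-parameter range-shifter model:
#' \deqn{\phi(\beta) = \int_{\beta_c}^{\beta}
#'   \frac{d\beta'}{\beta'^{4/3}(1-\beta'^2)^{4/3}},}
#' with \eqn{\chi} and \eqn{\psi} the nested integrals of \eqn{\phi} and
#' \eqn{\chi} against the weight
#' \eqn{1/(\beta'^{8/3}(1-\beta'^2)^{3/2})}. The lower cutoff `beta_cut` is
#' an arbitrary regularization of the singularity at zero speed; physically
#' meaningful results are entrance-minus-exit differences, which the model's
#' self-consistent material factor makes exactly cutoff-independent. The
#' weight antiderivative `w` is returned alongside because that factor is
#' built from it.
#'
#' @param beta Speed fraction(s), `beta_cut <= beta < 1` (vectorized).
#' @param beta_cut Lower integration cutoff in (0, min(beta)].
#' @param rel_tol Solver relative tolerance.
#' @return A data.frame with columns `beta`, `phi`, `chi`, `psi`, `w`, all
#'   zero at `beta = beta_cut` and strictly increasing.
#' @export
five_thirds_integrals <- function(beta, beta_cut = 0.05, rel_tol = 1e-11) {
  if (any(beta >= 1)) stop("beta must be below 1")
  if (beta_cut <= 0 || beta_cut >= 1) stop("beta_cut must lie in (0, 1)")
  if (any(beta < beta_cut)) stop("beta must be >= beta_cut")
  bs <- sort(unique(c(beta_cut, beta)))
  if (length(bs) == 1) {
    sol <- matrix(0, 1, 4)
  } else {
    out <- deSolve::ode(y = c(phi = 0, chi = 0, psi = 0, w = 0),
                        times = bs, func = five_thirds_rhs, parms = NULL,
                        method = "lsoda", rtol = rel_tol, atol = 1e-13)
    sol <- out[, -1, drop = FALSE]
  }
  idx <- match(beta, bs)
  data.frame(beta = beta, phi = sol[idx, 1], chi = sol[idx, 2],
             psi = sol[idx, 3], w = sol[idx, 4])
}
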