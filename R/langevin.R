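#' Langevin function
#'
#' Equilibrium magnetization fraction of an ensemble of superparamagnetic
#' particles, \eqn{\mathcal{L}(a) = \coth(a) - 1/a}. This is the scalar
#' nonlinearity at the heart of the MPI signal model: particles far from the
#' field-free line sit in a strong field, are saturated
#' (\eqn{\mathcal{L} \to 1}) and contribute no time-varying signal; only
#' particles near the line respond.
#'
#' The closed form suffers catastrophic cancellation near zero (both terms
#' diverge like \eqn{1/a}), so for \eqn{|a| < 10^{-2}} the Taylor expansion
#' \eqn{a/3 - a^3/45 + 2a^5/945 - a^7/4725} is used; its truncation error at
#' the crossover is below 1e-20 relative, so the switch is seamless.
#'
#' @param a Dimensionless field argument (typically \eqn{\beta \mu_0 \|H\|}).
#'   Any sign; the function is odd.
#' @return Values in (-1, 1), same shape as `a`.
#' @seealso [langevin_derivative()]
#' @examples
#' langevin(1)            # coth(1) - 1 = 0.31304...
#' langevin(c(-2, 0, 2))  # odd, zero at zero
#' @export
langevin <- function(a) {
  out <- a
  small <- abs(a) < 1e-2
  if (any(small)) {
    s <- a[small]
    s2 <- s * s
    out[small] <- s * (1 / 3 - s2 / 45 + 2 * s2 * s2 / 945 - s2^3 / 4725)
  }
  if (any(!small)) {
    b <- a[!small]
    out[!small] <- 1 / tanh(b) - 1 / b
  }
  out
}

#' Derivative of the Langevin function
#'
#' \eqn{\mathcal{L}'(a) = 1/a^2 - 1/\sinh^2(a)}, with the limit
#' \eqn{\mathcal{L}'(0) = 1/3}. Enters the analytic time derivative of the
#' received-signal integrand (the component of the point-spread tensor along
#' the local field direction).
#'
#' Uses the Taylor expansion \eqn{1/3 - a^2/15 + 2a^4/189 - a^6/675} for
#' \eqn{|a| < 10^{-2}} (the closed form cancels catastrophically there); for
#' large \eqn{|a|} the \eqn{1/\sinh^2} term underflows harmlessly to 0.
#'
#' @param a Dimensionless field argument.
#' @return Values in (0, 1/3], same shape as `a`.
#' @export
langevin_derivative <- function(a) {
  out <- a
  small <- abs(a) < 1e-2
  if (any(small)) {
    s2 <- a[small]^2
    out[small] <- 1 / 3 - s2 / 15 + 2 * s2 * s2 / 189 - s2^3 / 675
  }
  if (any(!small)) {
    b <- a[!small]
    # sinh overflows past ~710; there L' is 1/a^2 to machine precision
    big <- abs(b) > 350
    v <- numeric(length(b))
    v[big] <- 1 / b[big]^2
    v[!big] <- 1 / b[!big]^2 - 1 / sinh(b[!big])^2
    out[!small] <- v
  }
  out
}
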