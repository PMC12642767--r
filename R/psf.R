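#' Langevin point-spread tensor
#'
#' The 3x3 tensor \eqn{\bar h(u)} whose entries are the point-spread
#' functions of the FFL signal model. It arises from differentiating the
#' Langevin magnetization of a point source in time: with \eqn{w = G u},
#' \eqn{a = \beta\|w\|}, \eqn{\hat w = w/\|w\|}, the Jacobian of the map
#' \eqn{w \mapsto \mathcal{L}(\beta\|w\|)\, w/\|w\|} is
#' \deqn{J(w) = \frac{\mathcal{L}(a)}{\|w\|}\,(I - \hat w \hat w^\top)
#'              + \beta\,\mathcal{L}'(a)\, \hat w \hat w^\top,}
#' and \eqn{\bar h(u) = J(G u)\,G}. At \eqn{w = 0} the isotropic limit
#' \eqn{J = (\beta/3) I} applies, so \eqn{\bar h(0) = (\beta/3) G}. Because
#' `G`'s middle row and column vanish (the FFL is along y), the y row and
#' column of \eqn{\bar h} are identically zero: offsets along the line do not
#' change the field, and nothing couples into the y receive direction.
#'
#' The closed form is validated in the test suite against a brute-force
#' finite-difference oracle (numeric time derivative of the magnetization of
#' a point source over a drive period).
#'
#' @param model A [scanner_model()] (supplies G0).
#' @param particle A [particle_model()] (supplies beta).
#' @param u Length-3 spatial offset (m), or an n x 3 matrix of offsets.
#' @return A 3x3 matrix (units 1/m) for a single offset, or a 3x3xn array.
#' @export
psf_tensor <- function(model, particle, u) {
  single <- is.null(dim(u))
  u <- if (single) matrix(u, 1, 3) else as.matrix(u)
  stopifnot(ncol(u) == 3)
  G0 <- model$G0
  beta <- particle$beta
  wx <- -G0 * u[, 1]
  wz <- G0 * u[, 3]
  r <- sqrt(wx^2 + wz^2)
  a <- beta * r
  # L(a)/r -> beta/3 as r -> 0
  t1 <- ifelse(r > 0, langevin(a) / pmax(r, .Machine$double.xmin), beta / 3)
  t2 <- beta * langevin_derivative(a)
  hx <- ifelse(r > 0, wx / pmax(r, .Machine$double.xmin), 0)
  hz <- ifelse(r > 0, wz / pmax(r, .Machine$double.xmin), 0)
  d <- t2 - t1
  Jxx <- t1 + d * hx * hx
  Jxz <- d * hx * hz
  Jzz <- t1 + d * hz * hz
  out <- array(0, dim = c(3, 3, nrow(u)))
  out[1, 1, ] <- -G0 * Jxx
  out[1, 3, ] <- G0 * Jxz
  out[3, 1, ] <- -G0 * Jxz
  out[3, 3, ] <- G0 * Jzz
  if (single) out[, , 1] else out
}

# Sample the four nonzero PSF components h_{ij}, i,j in {x,z}, on the full
# linear-convolution offset grid (2 nx - 1) x (2 nz - 1) of an in-plane
# image grid. Returns list with matrices xx, xz, zx, zz.
.psf_kernels <- function(model, particle, grid) {
  sp <- grid$spacing
  nx <- grid$shape[1]
  nz <- grid$shape[length(grid$shape)]
  ux <- sp[1] * seq(-(nx - 1), nx - 1)
  uz <- sp[length(sp)] * seq(-(nz - 1), nz - 1)
  G0 <- model$G0
  beta <- particle$beta
  WX <- matrix(-G0 * ux, length(ux), length(uz))
  WZ <- matrix(G0 * uz, length(ux), length(uz), byrow = TRUE)
  r <- sqrt(WX^2 + WZ^2)
  a <- beta * r
  pos <- r > 0
  t1 <- matrix(beta / 3, nrow(r), ncol(r))
  t1[pos] <- langevin(a[pos]) / r[pos]
  t2 <- beta * langevin_derivative(a)
  hx <- matrix(0, nrow(r), ncol(r)); hx[pos] <- WX[pos] / r[pos]
  hz <- matrix(0, nrow(r), ncol(r)); hz[pos] <- WZ[pos] / r[pos]
  d <- t2 - t1
  list(xx = -G0 * (t1 + d * hx * hx),
       xz = G0 * (d * hx * hz),
       zx = -G0 * (d * hx * hz),
       zz = G0 * (t1 + d * hz * hz))
}
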