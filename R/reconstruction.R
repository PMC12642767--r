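# Tikhonov-regularized inversion of the block 3D model:
#   min_x ||A x - b||_2^2 + lambda ||T x||_2^2
# solved by fixed-step gradient descent with heavy-ball acceleration,
#   y_{k+1} = x_k + (k-1)/(k+2) (x_k - x_{k-1})
#   x_{k+1} = y_{k+1} - tau [ A^H (A y_{k+1} - b) + lambda T^T T y_{k+1} ]
#   tau     = 1 / ( ||A^H A||_2 (1 + safety) + lambda ||T^T T||_2 )
# with an optional projection of each iterate onto real nonnegative values.

#' First-order finite-difference operator and adjoint
#'
#' Forward differences along each axis of a (possibly complex) array, zero at
#' the far boundary; the regularizer `T` of the Tikhonov objective. The
#' adjoint is the negative divergence with the matching boundary convention,
#' so `T^T T` is the (negated) discrete Laplacian with
#' `||T^T T||_2 <= 4 * (number of axes)`.
#'
#' @param x Array (2D or 3D), or vector with `shape` supplied.
#' @param shape Integer dimensions of `x` if it is a plain vector.
#' @return `finite_difference`: list of arrays, one per axis.
#'   `finite_difference_adjoint`: a single array.
#' @export
finite_difference <- function(x, shape = dim(x)) {
  stopifnot(!is.null(shape))
  dim(x) <- shape
  nd <- length(shape)
  out <- vector("list", nd)
  for (ax in seq_len(nd)) {
    d <- array(0, shape)
    if (is.complex(x)) d <- d + 0i
    n <- shape[ax]
    if (n > 1) {
      idx_hi <- lapply(shape, seq_len); idx_hi[[ax]] <- 2:n
      idx_lo <- lapply(shape, seq_len); idx_lo[[ax]] <- 1:(n - 1)
      idx_to <- idx_lo
      d_part <- do.call(`[`, c(list(x), idx_hi, drop = FALSE)) -
        do.call(`[`, c(list(x), idx_lo, drop = FALSE))
      d <- do.call(`[<-`, c(list(d), idx_to, list(d_part)))
    }
    out[[ax]] <- d
  }
  out
}

#' @rdname finite_difference
#' @param d List of difference arrays (one per axis).
#' @export
finite_difference_adjoint <- function(d, shape = dim(d[[1]])) {
  nd <- length(d)
  acc <- array(0, shape)
  if (any(vapply(d, is.complex, logical(1)))) acc <- acc + 0i
  for (ax in seq_len(nd)) {
    di <- d[[ax]]; dim(di) <- shape
    n <- shape[ax]
    if (n > 1) {
      idx_hi <- lapply(shape, seq_len); idx_hi[[ax]] <- 2:n
      idx_lo <- lapply(shape, seq_len); idx_lo[[ax]] <- 1:(n - 1)
      lo <- do.call(`[`, c(list(di), idx_lo, drop = FALSE))
      acc <- do.call(`[<-`, c(list(acc), idx_lo,
                              list(do.call(`[`, c(list(acc), idx_lo, drop = FALSE)) - lo)))
      acc <- do.call(`[<-`, c(list(acc), idx_hi,
                              list(do.call(`[`, c(list(acc), idx_hi, drop = FALSE)) + lo)))
    }
  }
  acc
}

# T^T T applied to a vectorized array
.laplacian_quad <- function(x, shape) {
  as.vector(finite_difference_adjoint(finite_difference(x, shape), shape))
}

#' Largest-eigenvalue estimate by power iteration
#'
#' Estimates the spectral norm of a self-adjoint positive semi-definite map
#' (a normal-equations form such as `A^H A` or `T^T T`) by seeded power
#' iteration with a fixed iteration count, so results are reproducible.
#'
#' @param apply_fn Function of one vector returning the map applied to it.
#' @param n Input dimension.
#' @param seed RNG seed for the start vector.
#' @param iterations Number of power iterations (default 30).
#' @return Nonnegative scalar estimate of the top eigenvalue (0 for the zero
#'   operator).
#' @export
estimate_operator_norm <- function(apply_fn, n, seed = 1L, iterations = 30L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v <- stats::rnorm(n)
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(iterations)) {
    w <- apply_fn(v)
    nw <- sqrt(sum(Mod(w)^2))
    if (nw == 0) return(0)
    lam <- Re(sum(Conj(v) * w))
    v <- w / nw
  }
  max(lam, 0)
}

#' Tikhonov objective value
#'
#' `||A x - b||_2^2 + lambda ||T x||_2^2`, with complex moduli in the
#' residual norm.
#'
#' @param x Current volume (vector).
#' @param forward Function applying `A`.
#' @param b Data vector.
#' @param lambda Regularization weight.
#' @param shape Array dimensions of `x` (for the finite-difference term).
#' @return Nonnegative scalar.
#' @export
tikhonov_objective <- function(x, forward, b, lambda, shape) {
  r <- forward(x) - b
  fid <- sum(Mod(r)^2)
  reg <- if (lambda > 0) {
    sum(vapply(finite_difference(x, shape), function(d) sum(Mod(d)^2), numeric(1)))
  } else 0
  fid + lambda * reg
}

#' Reconstruction configuration
#'
#' @param lambda Regularization weight, >= 0.
#' @param iterations Iteration count (default 150).
#' @param projection `"real_nonneg"` (project each iterate onto real
#'   nonnegative values) or `"none"`.
#' @param norm_iterations,norm_seed Power-iteration settings for the step
#'   length.
#' @param safety Inflation factor on the estimated `||A^H A||_2` guarding
#'   against power-iteration under-estimates (default 0.05).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(lambda = 0, iterations = 150L,
                         projection = c("real_nonneg", "none"),
                         norm_iterations = 30L, norm_seed = 1L,
                         safety = 0.05) {
  projection <- match.arg(projection)
  stopifnot(lambda >= 0, iterations >= 1, norm_iterations >= 1, safety >= 0)
  structure(list(lambda = lambda, iterations = as.integer(iterations),
                 projection = projection,
                 norm_iterations = as.integer(norm_iterations),
                 norm_seed = as.integer(norm_seed), safety = safety),
            class = "recon_config")
}

#' Heavy-ball Tikhonov solver
#'
#' Accelerated projected gradient descent on the Tikhonov objective. The
#' step length is `1 / (estimate(||A^H A||) * (1 + safety) + lambda *
#' estimate(||T^T T||))`; iterates start at zero, are stored complex while
#' iterating (the adjoint of complex data is complex) and are projected to
#' real nonnegative values after each update when the projection is enabled.
#' The recorded objective trace is evaluated at the extrapolated points,
#' where the residual is computed anyway; its first entry is the objective
#' at zero.
#'
#' @param forward Function: volume vector -> data vector (`A`).
#' @param adjoint Function: data vector -> volume vector (`A^H`).
#' @param b Data vector.
#' @param shape Array dimensions of the volume.
#' @param config A [recon_config()].
#' @param tau Optional explicit step length; estimated when `NULL`.
#' @return List with `volume` (array, real when projected), `objective`
#'   (trace), `tau`, `norm_AHA`, `norm_TtT`, `config`.
#' @export
solve_tikhonov <- function(forward, adjoint, b, shape,
                           config = recon_config(), tau = NULL) {
  n <- prod(shape)
  lambda <- config$lambda
  norm_A <- norm_T <- NA_real_
  if (is.null(tau)) {
    norm_A <- estimate_operator_norm(function(v) adjoint(forward(v)), n,
                                     seed = config$norm_seed,
                                     iterations = config$norm_iterations)
    norm_T <- if (lambda > 0) {
      estimate_operator_norm(function(v) .laplacian_quad(v, shape), n,
                             seed = config$norm_seed,
                             iterations = config$norm_iterations)
    } else 0
    denom <- norm_A * (1 + config$safety) + lambda * norm_T
    if (denom <= 0) stop("operator norm estimate is zero; cannot set step length")
    tau <- 1 / denom
  }
  x <- complex(n)
  x_prev <- x
  trace <- numeric(config$iterations)
  for (k in seq_len(config$iterations)) {
    y <- x + ((k - 1) / (k + 2)) * (x - x_prev)
    r <- forward(y) - b
    g <- adjoint(r)
    if (lambda > 0) g <- g + lambda * .laplacian_quad(y, shape)
    obj <- sum(Mod(r)^2)
    if (lambda > 0) {
      obj <- obj + lambda * sum(vapply(finite_difference(y, shape),
                                       function(d) sum(Mod(d)^2), numeric(1)))
    }
    if (!is.finite(obj)) stop("non-finite objective at iteration ", k,
                              "; aborting (check scaling / step length)")
    trace[k] <- obj
    x_prev <- x
    x <- y - tau * g
    if (config$projection == "real_nonneg") {
      x <- as.complex(pmax(Re(x), 0))
    }
  }
  vol <- if (config$projection == "real_nonneg") Re(x) else x
  dim(vol) <- shape
  list(volume = vol, objective = trace, tau = tau,
       norm_AHA = norm_A, norm_TtT = norm_T, config = config)
}

#' Reconstruct a 3D volume from multi-angle harmonic data
#'
#' Convenience wrapper binding [mpi_model_3d()] to [solve_tikhonov()].
#'
#' @param m3 An [mpi_model_3d()].
#' @param b Complex data vector (or list of [harmonic_block()]s) ordered as
#'   produced by [forward_A()] / [simulate_scan()].
#' @param config A [recon_config()].
#' @return As [solve_tikhonov()], with `volume` shaped to the model grid.
#' @export
mpi_reconstruct <- function(m3, b, config = recon_config()) {
  if (is.list(b)) b <- unlist(lapply(b, function(x) x$coefficients))
  solve_tikhonov(function(v) forward_A(v, m3),
                 function(d) adjoint_A(d, m3),
                 b, m3$volume_grid$shape, config)
}
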