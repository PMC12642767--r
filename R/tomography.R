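# Parallel-beam coupling of 3D volumes to the 2D FFL model.
#
# Rotating the scanner hardware about the z-axis by theta is modeled
# equivalently as rotating the density and keeping the magnetic model
# stationary: the angular projection rho_theta(x', z) = integral of
# rho(Q_theta (x', y')^T, z) over y' is a standard parallel-beam projection,
# discretized here as a sparse operator.

#' Projection angle set
#'
#' Equally spaced angles over the half-open range `[0, 180)` degrees,
#' rotation about the z-axis (counterclockwise viewed from +z).
#'
#' @param n Number of angles (default 21).
#' @param angles Explicit angles in degrees (overrides `n`); must lie in
#'   `[0, 180)`.
#' @return Numeric vector of class `angle_set`.
#' @export
angle_set <- function(n = 21, angles = NULL) {
  if (is.null(angles)) {
    angles <- seq(0, 180, length.out = n + 1)[seq_len(n)]
  }
  angles <- as.numeric(angles)
  stopifnot(all(angles >= 0), all(angles < 180))
  structure(angles, class = "angle_set")
}

#' In-plane rotation matrix action
#'
#' Applies \eqn{Q_\theta = [\cos\theta, \sin\theta; -\sin\theta, \cos\theta]}
#' to (x, y) coordinates: the map from projection-frame to volume-frame
#' in-plane coordinates.
#'
#' @param theta Angle in degrees.
#' @param xy Length-2 vector or n x 2 matrix.
#' @return Rotated coordinates, same shape as `xy`.
#' @export
rotate_coords <- function(theta, xy) {
  th <- theta * pi / 180
  Q <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  if (is.null(dim(xy))) as.vector(Q %*% xy) else t(Q %*% t(xy))
}

#' Sparse parallel-beam projector at one angle
#'
#' Builds the sparse matrix `P_theta` mapping a vectorized 3D volume
#' (x fastest, then y, then z) to a vectorized 2D projection (x' fastest,
#' then z). Each voxel's line integral along the rotated y-direction is
#' deposited at its rotated in-plane coordinate
#' `x' = cos(theta) x - sin(theta) y` with linear (tent) weights on the
#' detector axis, scaled by `dx dy / dx'`; the z axis passes through
#' unchanged. Voxel centers land exactly on detector nodes at multiples of
#' 90 degrees, so axis-aligned projections reduce to exact permutation sums,
#' and total mass (`sum * cell measure`) is conserved exactly for any angle
#' whenever the rotated support stays inside the detector grid (splats
#' falling outside are dropped, consistently in forward and adjoint). The
#' adjoint (backprojection) is the matrix transpose.
#'
#' @param theta Angle in degrees.
#' @param volume_grid 3D [image_grid()].
#' @param proj_grid 2D [image_grid()] for (x', z); its z axis must match the
#'   volume's z axis exactly.
#' @return A `dgCMatrix` of dimension `prod(proj_grid$shape)` x
#'   `prod(volume_grid$shape)`.
#' @export
build_projector <- function(theta, volume_grid, proj_grid) {
  stopifnot(volume_grid$dims == 3L, proj_grid$dims == 2L)
  if (proj_grid$shape[2] != volume_grid$shape[3] ||
      abs(proj_grid$spacing[2] - volume_grid$spacing[3]) > 1e-12) {
    stop("projection grid z axis must match the volume grid z axis")
  }
  nx <- volume_grid$shape[1]; ny <- volume_grid$shape[2]
  nz <- volume_grid$shape[3]
  npx <- proj_grid$shape[1]
  th <- theta * pi / 180
  xv <- rep(grid_axis(volume_grid, 1), times = ny)
  yv <- rep(grid_axis(volume_grid, 2), each = nx)
  xp <- cos(th) * xv - sin(th) * yv
  fx <- (xp - proj_grid$origin[1]) / proj_grid$spacing[1] + 1
  i0 <- floor(fx + 1e-9)  # snap exact node hits
  wx <- fx - i0
  on_node <- abs(wx) < 1e-9
  wx[on_node] <- 0
  wgt <- volume_grid$spacing[1] * volume_grid$spacing[2] / proj_grid$spacing[1]
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (d in 0:1) {
    ii <- i0 + d
    w <- if (d == 0) 1 - wx else wx
    ok <- ii >= 1 & ii <= npx & w > 0
    rows <- c(rows, ii[ok]); cols <- c(cols, which(ok)); vals <- c(vals, w[ok] * wgt)
  }
  # replicate the in-plane pattern over z slabs
  nxy <- nx * ny
  rows_all <- rep(rows, nz) + npx * rep(seq_len(nz) - 1, each = length(rows))
  cols_all <- rep(cols, nz) + nxy * rep(seq_len(nz) - 1, each = length(cols))
  Matrix::sparseMatrix(i = rows_all, j = cols_all, x = rep(vals, nz),
                       dims = c(npx * nz, nx * ny * nz))
}

#' Block 3D FFL forward model over all projection angles
#'
#' Assembles the complete operator of the multi-angle 3D model: per angle,
#' the sparse projector followed by the compressed 2D forward operator, for
#' both drive axes (each angle carries an x-drive and a z-drive scan, all
#' sharing one scan sequence). The forward map takes a 3D density to the
#' stacked harmonic coefficient vector ordered by (angle, drive axis); the
#' adjoint accumulates backprojected adjoint images over all blocks.
#'
#' @param volume_grid 3D [image_grid()].
#' @param model A [scanner_model()]; both drive axes are derived from it.
#' @param particle A [particle_model()].
#' @param angles An [angle_set()] or numeric vector of degrees.
#' @param drive_axes Character subset of `c("x", "z")`.
#' @param K,bandwidth,transfer Compression settings, see [mpi_operator()].
#' @return An object of class `mpi_model_3d` with precomputed projectors and
#'   per-axis 2D operators, plus `n_data` (complex data length) and
#'   `n_voxel`.
#' @export
mpi_model_3d <- function(volume_grid, model, particle, angles,
                         drive_axes = c("x", "z"), K = 5, bandwidth = 500,
                         transfer = NULL) {
  stopifnot(volume_grid$dims == 3L)
  drive_axes <- match.arg(drive_axes, c("x", "z"), several.ok = TRUE)
  angles <- as.numeric(angles)
  proj_grid <- image_grid(volume_grid$shape[c(1, 3)],
                          volume_grid$spacing[c(1, 3)])
  projectors <- lapply(angles, build_projector,
                       volume_grid = volume_grid, proj_grid = proj_grid)
  ops <- lapply(drive_axes, function(ax) {
    m <- model
    m$drive_axis <- ax
    if (identical(unname(model$receive_sensitivity[model$drive_axis]), 1) &&
        sum(model$receive_sensitivity != 0) == 1) {
      b <- c(x = 0, y = 0, z = 0); b[ax] <- 1
      m$receive_sensitivity <- b
    }
    mpi_operator(proj_grid, m, particle, K = K, bandwidth = bandwidth,
                 transfer = transfer)
  })
  names(ops) <- drive_axes
  block_len <- length(unlist(ops[[1]]$bands %||% list(seq_len(ops[[1]]$n_time))))
  structure(list(
    volume_grid = volume_grid, proj_grid = proj_grid,
    model = model, particle = particle,
    angles = angles, drive_axes = drive_axes,
    projectors = projectors,
    projectors_t = lapply(projectors, Matrix::t),
    ops = ops,
    block_len = block_len,
    n_data = block_len * length(angles) * length(drive_axes),
    n_voxel = prod(volume_grid$shape)
  ), class = "mpi_model_3d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mpi_model_3d <- function(x, ...) {
  cat(sprintf(
    "<mpi_model_3d> volume %s, %d angles x %d drive axes, %d complex data/scan\n",
    paste(x$volume_grid$shape, collapse = " x "), length(x$angles),
    length(x$drive_axes), x$block_len))
  invisible(x)
}

#' Apply the block 3D model and its adjoint
#'
#' `apply_A` returns the harmonic blocks per (angle, drive axis);
#' `forward_A` / `adjoint_A` are the vectorized maps used by the solver
#' (complex data vector ordered angle-major, drive axis within angle).
#'
#' @param rho3d 3D array (or vector) on the model's volume grid; may be
#'   complex during iterative inversion.
#' @param m3 An [mpi_model_3d()].
#' @return `apply_A`: list of [harmonic_block()]s. `forward_A`: complex
#'   vector of length `m3$n_data`. `adjoint_A`: complex volume vector.
#' @export
apply_A <- function(rho3d, m3) {
  rho <- as.vector(rho3d)
  stopifnot(length(rho) == m3$n_voxel)
  out <- list()
  for (mi in seq_along(m3$angles)) {
    p <- .spmul(m3$projectors[[mi]], rho)
    for (ax in m3$drive_axes) {
      out[[length(out) + 1]] <-
        apply_ADC(matrix(p, m3$proj_grid$shape[1], m3$proj_grid$shape[2]),
                  m3$ops[[ax]], drive_axis = ax, angle = m3$angles[mi])
    }
  }
  out
}

#' @rdname apply_A
#' @export
forward_A <- function(rho3d, m3) {
  unlist(lapply(apply_A(rho3d, m3), function(b) b$coefficients))
}

#' @rdname apply_A
#' @param b Complex data vector of length `m3$n_data` (or list of blocks).
#' @export
adjoint_A <- function(b, m3) {
  if (is.list(b)) b <- unlist(lapply(b, function(x) x$coefficients))
  stopifnot(length(b) == m3$n_data)
  acc <- complex(m3$n_voxel)
  k <- 0L
  for (mi in seq_along(m3$angles)) {
    Pt <- m3$projectors_t[[mi]]
    for (ax in m3$drive_axes) {
      blk <- b[(k + 1):(k + m3$block_len)]
      k <- k + m3$block_len
      img <- adjoint_ADC(blk, m3$ops[[ax]])
      acc <- acc + as.vector(.spmul(Pt, as.vector(img)))
    }
  }
  acc
}
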