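# Shared fixtures: a small, fast scan configuration whose FFL trajectory
# stays strictly inside a 16 x 16 in-plane grid (1.6 mm FOV), so operator
# pipelines can be compared against brute-force oracles without boundary
# effects. 4800 time samples per scan.

tiny_scanner <- function(drive_axis = "z") {
  scanner_model(drive_amplitude = 4e-3,
                drive_axis = drive_axis,
                fov = c(x = 1.6e-3, y = 1.6e-3, z = 1.6e-3),
                sample_rate = 480e3,
                raster = list(n_lines = 2L, line_period = 0.005,
                              x_amplitude = 0.6e-3, z_extent = 0.04e-3))
}

tiny_grid <- function(n = 16) image_grid(c(n, n), 1.6e-3 / n)

tiny_op <- function(n = 16, drive_axis = "z", K = 5, bandwidth = 500) {
  mpi_operator(tiny_grid(n), tiny_scanner(drive_axis), particle_model(),
               K = K, bandwidth = bandwidth)
}

# small 3D study: 12^3 volume, trajectory inside the FOV
tiny_study3d <- function(n = 12, n_angles = 3) {
  grid <- image_grid(c(n, n, n), 1.6e-3 / n)
  model <- tiny_scanner()
  model$fov <- c(x = 1.6e-3, y = 1.6e-3, z = 1.6e-3)
  m3 <- mpi_model_3d(grid, model, particle_model(), angle_set(n_angles))
  list(grid = grid, model = model, m3 = m3)
}

rel_l2 <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}

# normalized adjoint dot-test error |<Ax,y> - <x,A^H y>| / (|Ax| |y|)
dot_test <- function(fwd, adj, n_in, n_out, draws = 5, seed = 42,
                     complex_in = FALSE, complex_out = FALSE) {
  set.seed(seed)
  errs <- numeric(draws)
  for (d in seq_len(draws)) {
    x <- if (complex_in) complex(real = rnorm(n_in), imaginary = rnorm(n_in))
         else rnorm(n_in)
    y <- if (complex_out) complex(real = rnorm(n_out), imaginary = rnorm(n_out))
         else rnorm(n_out)
    ax <- fwd(x)
    aty <- adj(y)
    lhs <- sum(ax * Conj(y))
    rhs <- sum(x * Conj(aty))
    errs[d] <- Mod(lhs - rhs) / (sqrt(sum(Mod(ax)^2)) * sqrt(sum(Mod(y)^2)))
  }
  max(errs)
}

# Brute-force received signal: direct summation of the Langevin
# magnetization over the grid, numeric time derivative with a tiny step.
# The independent oracle for the operator pipeline.
brute_force_signal <- function(model, particle, rho, grid, dt = 1e-10) {
  xs <- grid_axis(grid, 1); zs <- grid_axis(grid, 2)
  pts <- cbind(rep(xs, length(zs)), rep(zs, each = length(xs)))
  w <- as.vector(rho)
  bsum <- function(tt) {
    HD <- drive_field(model, tt)
    Hx <- outer(HD[, 1], model$G0 * pts[, 1], "+")
    Hz <- outer(HD[, 3], -model$G0 * pts[, 2], "+")
    r <- sqrt(Hx^2 + Hz^2)
    L <- matrix(particle$beta / 3, nrow(r), ncol(r))
    pos <- r > 0
    L[pos] <- langevin(particle$beta * r[pos]) / r[pos]
    bv <- model$receive_sensitivity
    as.vector((L * (bv[["x"]] * Hx + bv[["z"]] * Hz)) %*% w)
  }
  t <- scan_times(model)
  particle$m * (bsum(t + 2 * dt) - bsum(t)) / (2 * dt) * prod(grid$spacing)
}

# dense rotate-then-sum projection oracle (bilinear resampling of the
# rotated volume, summed along y and scaled by the voxel length)
rotate_sum_oracle <- function(vol, grid, theta) {
  n1 <- dim(vol)[1]; n2 <- dim(vol)[2]; n3 <- dim(vol)[3]
  ax <- grid_axis(grid, 1); ay <- grid_axis(grid, 2)
  th <- theta * pi / 180
  xp <- rep(ax, times = n2); yp <- rep(ay, each = n1)
  xs <- cos(th) * xp + sin(th) * yp
  ys <- -sin(th) * xp + cos(th) * yp
  fx <- (xs - ax[1]) / grid$spacing[1] + 1
  fy <- (ys - ay[1]) / grid$spacing[2] + 1
  i0 <- floor(fx); j0 <- floor(fy); wx <- fx - i0; wy <- fy - j0
  out <- matrix(0, n1, n3)
  for (k in seq_len(n3)) {
    sl <- vol[, , k]
    acc <- numeric(n1 * n2)
    for (dx in 0:1) for (dy in 0:1) {
      ii <- i0 + dx; jj <- j0 + dy
      w <- (if (dx == 0) 1 - wx else wx) * (if (dy == 0) 1 - wy else wy)
      ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
      acc[ok] <- acc[ok] + w[ok] * sl[cbind(ii[ok], jj[ok])]
    }
    out[, k] <- rowSums(matrix(acc, n1, n2)) * grid$spacing[2]
  }
  out
}

# smooth 3D Gaussian blob phantom on a grid
gaussian_blob <- function(grid, center = c(0, 0, 0), sigma) {
  ax <- grid_axis(grid, 1); ay <- grid_axis(grid, 2); az <- grid_axis(grid, 3)
  gx <- exp(-(ax - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(ay - center[2])^2 / (2 * sigma^2))
  gz <- exp(-(az - center[3])^2 / (2 * sigma^2))
  outer(outer(gx, gy), gz)
}
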