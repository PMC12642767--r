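# Discrete forward-model operators.
#
# The continuous signal model
#   s0(t) = m * sum_ij  integral rho(x) b_i(x) h_ij(xi(t) - x) v_j(t) dx
# factors into a chain of linear operators applied to the in-plane density:
#   B  receive-sensitivity weighting (3 images)
#   H  convolution with the Langevin PSF tensor (9 images C_ij)
#   E  sampling of each C_ij along the FFL trajectory (bilinear)
#   V  velocity weighting and summation into the time signal
#   Gamma  receive-chain notch filter (Fourier-domain diagonal)
# and the compressed operator  A_DC = S D_Gamma F V E H B  needs a single
# forward FFT per application. All components are precomputed once into an
# `mpi_operator` object and reused across solver iterations.

.AXES <- c("x", "y", "z")
.INPLANE <- c("x", "z")

# 2D FFT helpers (stats::fft is multi-dimensional on matrices)
.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# sparse-matrix times possibly-complex dense matrix/vector
.spmul <- function(M, X) {
  X <- as.matrix(X)
  if (is.complex(X)) {
    as.matrix(M %*% Re(X)) + 1i * as.matrix(M %*% Im(X))
  } else {
    as.matrix(M %*% X)
  }
}

# Bilinear interpolation matrix: rows = trajectory samples, cols = voxels of
# the in-plane grid (column-major x fastest). Samples outside the grid
# contribute zero (and receive zero splat in the adjoint).
.bilinear_matrix <- function(grid, pts) {
  nx <- grid$shape[1]; nz <- grid$shape[2]
  fx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1
  fz <- (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1
  i0 <- floor(fx); j0 <- floor(fz)
  wx <- fx - i0; wz <- fz - j0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (dx in 0:1) {
    for (dz in 0:1) {
      ii <- i0 + dx; jj <- j0 + dz
      w <- (if (dx == 0) 1 - wx else wx) * (if (dz == 0) 1 - wz else wz)
      ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= nz & w > 0
      rows <- c(rows, which(ok))
      cols <- c(cols, ii[ok] + (jj[ok] - 1) * nx)
      vals <- c(vals, w[ok])
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nrow(pts), nx * nz))
}

#' Precomputed FFL forward operator for one scan sequence
#'
#' Assembles everything the operator chain needs — PSF kernel FFTs, the
#' trajectory interpolation matrix, velocity weights, the notch transfer
#' function, and the harmonic band layout — for a fixed scanner, particle and
#' in-plane (x, z) reconstruction grid. The same object serves every
#' projection angle, since all angles share one scan sequence.
#'
#' @param grid A 2D [image_grid()] (the in-plane x, z mesh).
#' @param model A [scanner_model()].
#' @param particle A [particle_model()].
#' @param K Highest retained harmonic (bands cover `k = 2..K`); `NULL`
#'   disables compression so the "harmonic block" carries the full
#'   notch-filtered spectrum.
#' @param bandwidth Total bandwidth (Hz) retained around each harmonic
#'   (i.e. bins with `|f - k f0| <= bandwidth / 2`).
#' @param transfer Optional receive transfer function: a function of the
#'   folded frequency (Hz) returning complex gain. Default is unit gain and
#'   zero phase outside the notch.
#' @return An object of class `mpi_operator`.
#' @export
mpi_operator <- function(grid, model, particle, K = 5, bandwidth = 500,
                         transfer = NULL) {
  stopifnot(inherits(grid, "image_grid"), grid$dims == 2L,
            inherits(model, "scanner_model"), inherits(particle, "particle_model"))
  extent <- grid$shape * grid$spacing
  if (any(extent > model$fov[c("x", "z")] * (1 + 1e-9))) {
    warning("reconstruction grid extent exceeds the scanner FOV")
  }
  t <- scan_times(model)
  n <- length(t)
  fs <- model$sample_rate
  f0 <- model$drive_frequency
  xi <- ffl_position(model, t)
  v <- ffl_velocity(model, t)
  E <- .bilinear_matrix(grid, xi)
  if (Matrix::nnzero(E) == 0) {
    stop("FFL trajectory lies entirely outside the reconstruction grid")
  }
  ker <- .psf_kernels(model, particle, grid)
  nx <- grid$shape[1]; nz <- grid$shape[2]
  px <- 3L * nx - 2L; pz <- 3L * nz - 2L
  padk <- function(k) {
    p <- matrix(0, px, pz)
    p[seq_len(2 * nx - 1), seq_len(2 * nz - 1)] <- k
    .fft2(p)
  }
  kfft <- lapply(ker, padk)
  kfft_flip <- lapply(ker, function(k) padk(k[rev(seq_len(2 * nx - 1)),
                                             rev(seq_len(2 * nz - 1))]))
  f <- (seq_len(n) - 1) * fs / n
  ffold <- pmin(f, fs - f)
  gain <- if (is.null(transfer)) rep(1 + 0i, n) else as.complex(transfer(ffold))
  gain[abs(ffold - f0) <= model$notch_halfwidth] <- 0 + 0i
  bands <- NULL
  if (!is.null(K)) {
    stopifnot(K >= 2)
    if (K * f0 + bandwidth / 2 > fs / 2) {
      stop("harmonic band K*f0 + bandwidth/2 exceeds the Nyquist frequency")
    }
    npos <- floor(n / 2) + 1
    bands <- lapply(2:K, function(k) {
      which(abs(f - k * f0) <= bandwidth / 2 & seq_len(n) <= npos)
    })
    names(bands) <- paste0("k", 2:K)
    allb <- unlist(bands)
    if (anyDuplicated(allb)) stop("harmonic bands overlap; reduce bandwidth")
    if (any(lengths(bands) == 0)) stop("empty harmonic band; increase scan duration")
  }
  structure(list(
    grid = grid, model = model, particle = particle,
    n_time = n, times = t, velocity = v,
    E = E, Et = Matrix::t(E),
    kfft = kfft, kfft_flip = kfft_flip,
    pad = c(px, pz), cell = .cell_measure(grid),
    freqs = f, gamma = gain,
    transfer_real = is.null(transfer),
    K = K, bandwidth = bandwidth, bands = bands
  ), class = "mpi_operator")
}

#' @export
print.mpi_operator <- function(x, ...) {
  cat(sprintf("<mpi_operator> grid %s, %d time samples, %s\n",
              paste(x$grid$shape, collapse = " x "), x$n_time,
              if (is.null(x$K)) "uncompressed"
              else sprintf("harmonics 2..%d @ %.3g Hz (%d bins)",
                           x$K, x$bandwidth, length(unlist(x$bands)))))
  invisible(x)
}

.zero_image <- function(op) matrix(0, op$grid$shape[1], op$grid$shape[2])

.as_image <- function(op, rho) {
  if (is.null(dim(rho))) {
    stopifnot(length(rho) == prod(op$grid$shape))
    dim(rho) <- op$grid$shape
  } else {
    stopifnot(all(dim(rho) == op$grid$shape))
  }
  rho
}

#' Receive-sensitivity weighting operator B
#'
#' Pointwise multiplication of the in-plane density by each component of the
#' (homogeneous) receive sensitivity. With the default sensitivity along the
#' drive axis exactly one of the three weighted images is nonzero.
#'
#' @param rho In-plane density: matrix matching the operator grid, or its
#'   vectorization.
#' @param op An [mpi_operator()].
#' @return `apply_B`: list of three images named `x`, `y`, `z`.
#'   `adjoint_B`: a single image.
#' @export
apply_B <- function(rho, op) {
  rho <- .as_image(op, rho)
  b <- op$model$receive_sensitivity
  out <- lapply(.AXES, function(i) if (b[[i]] != 0) b[[i]] * rho else .zero_image(op))
  names(out) <- .AXES
  out
}

#' @rdname apply_B
#' @param images List of three images (as produced by `apply_B`).
#' @export
adjoint_B <- function(images, op) {
  b <- op$model$receive_sensitivity
  out <- .zero_image(op)
  for (i in .AXES) if (b[[i]] != 0) out <- out + b[[i]] * images[[i]]
  out
}

.conv_one <- function(op, img, kf) {
  nx <- op$grid$shape[1]; nz <- op$grid$shape[2]
  p <- matrix(0 + 0i, op$pad[1], op$pad[2])
  p[seq_len(nx), seq_len(nz)] <- img
  full <- .ifft2(.fft2(p) * kf)
  out <- full[nx:(2 * nx - 1), nz:(2 * nz - 1)] * op$cell
  if (!is.complex(img)) Re(out) else out
}

#' Langevin PSF convolution operator H
#'
#' Convolves each sensitivity-weighted image with the sampled PSF tensor
#' components: `C_ij = (b_i rho) * h_ij` (linear convolution via
#' zero-padded FFTs, scaled by the cell area, cropped back to the grid).
#' Components with a y index are identically zero for the FFL gradient, and
#' all-zero inputs are skipped.
#'
#' @param images List of three weighted images (`x`, `y`, `z`).
#' @param op An [mpi_operator()].
#' @return `apply_H`: nested list `C[[i]][[j]]` over `i, j` in `x, y, z`.
#'   `adjoint_H`: list of three images.
#' @export
apply_H <- function(images, op) {
  C <- lapply(.AXES, function(i) {
    img <- images[[i]]
    row <- lapply(.AXES, function(j) {
      kn <- paste0(i, j)
      if (i %in% .INPLANE && j %in% .INPLANE && any(img != 0)) {
        .conv_one(op, img, op$kfft[[kn]])
      } else {
        .zero_image(op)
      }
    })
    names(row) <- .AXES
    row
  })
  names(C) <- .AXES
  C
}

#' @rdname apply_H
#' @param C Nested list of convolved images `C[[i]][[j]]`.
#' @export
adjoint_H <- function(C, op) {
  out <- lapply(.AXES, function(i) {
    acc <- .zero_image(op)
    for (j in .INPLANE) {
      if (i %in% .INPLANE && any(C[[i]][[j]] != 0)) {
        acc <- acc + .conv_one(op, C[[i]][[j]], op$kfft_flip[[paste0(i, j)]])
      }
    }
    acc
  })
  names(out) <- .AXES
  out
}

#' Trajectory sampling operator E
#'
#' Samples each convolved image along the FFL trajectory by bilinear
#' interpolation; trajectory samples outside the grid contribute zero. The
#' adjoint splats the time series back onto the grid with the transposed
#' interpolation weights.
#'
#' @param C Nested list of images `C[[i]][[j]]`.
#' @param op An [mpi_operator()].
#' @return `apply_E`: nested list of time series (length `op$n_time`).
#'   `adjoint_E`: nested list of images.
#' @export
apply_E <- function(C, op) {
  out <- lapply(.AXES, function(i) {
    row <- lapply(.AXES, function(j) {
      img <- C[[i]][[j]]
      if (any(img != 0)) {
        as.vector(.spmul(op$E, as.vector(img)))
      } else {
        numeric(op$n_time)
      }
    })
    names(row) <- .AXES
    row
  })
  names(out) <- .AXES
  out
}

#' @rdname apply_E
#' @param series Nested list of time series.
#' @export
adjoint_E <- function(series, op) {
  out <- lapply(.AXES, function(i) {
    row <- lapply(.AXES, function(j) {
      s <- series[[i]][[j]]
      if (any(s != 0)) {
        m <- .spmul(op$Et, s)
        img <- as.vector(m)
        dim(img) <- op$grid$shape
        img
      } else {
        .zero_image(op)
      }
    })
    names(row) <- .AXES
    row
  })
  names(out) <- .AXES
  out
}

#' Velocity weighting operator V
#'
#' Combines the trajectory-sampled series into the raw received signal:
#' `s0(t) = m * sum_ij v_j(t) series_ij(t)` where `v` is the analytic FFL
#' velocity. The adjoint spreads a signal back over the `(i, j)` series as
#' `m * v_j(t) * s(t)`.
#'
#' @param series Nested list of time series.
#' @param op An [mpi_operator()].
#' @return `apply_V`: signal vector of length `op$n_time`.
#'   `adjoint_V`: nested list of time series.
#' @export
apply_V <- function(series, op) {
  s <- numeric(op$n_time)
  for (i in .AXES) {
    for (j in .INPLANE) {
      sj <- series[[i]][[j]]
      if (any(sj != 0)) s <- s + op$velocity[, j] * sj
    }
  }
  op$particle$m * s
}

#' @rdname apply_V
#' @param s Signal vector.
#' @export
adjoint_V <- function(s, op) {
  out <- lapply(.AXES, function(i) {
    row <- lapply(.AXES, function(j) {
      if (j %in% .INPLANE) op$particle$m * op$velocity[, j] * s
      else numeric(op$n_time)
    })
    names(row) <- .AXES
    row
  })
  names(out) <- .AXES
  out
}

# Fused adjoint of the V E H B chain. Receive components with zero
# sensitivity are annihilated by adjoint_B at the end of the chain, so their
# series are never splatted; the result is identical to the composition of
# the individual adjoints.
.adjoint_VEHB <- function(s, op) {
  b <- op$model$receive_sensitivity
  live <- .AXES[b != 0]
  out <- .zero_image(op)
  if (is.complex(s)) out <- out + 0i
  for (i in live) {
    if (!(i %in% .INPLANE)) next  # h_ij has a zero y row
    for (j in .INPLANE) {
      series <- op$particle$m * op$velocity[, j] * s
      img <- .spmul(op$Et, series)
      dim(img) <- op$grid$shape
      out <- out + b[[i]] * .conv_one(op, img, op$kfft_flip[[paste0(i, j)]])
    }
  }
  out
}

#' Receive-chain notch filter Gamma
#'
#' Fourier-domain multiplication by the receive transfer function: zero gain
#' in the notch `|f - f0| <= notch_halfwidth` (folded frequency), the
#' supplied transfer (default unit gain, zero phase) elsewhere. The adjoint
#' multiplies by the complex conjugate transfer.
#'
#' @param s Signal vector (or [time_signal()]).
#' @param op An [mpi_operator()].
#' @return Filtered signal vector (real when the input and transfer are real).
#' @export
apply_Gamma <- function(s, op) {
  if (inherits(s, "time_signal")) s <- s$samples
  out <- stats::fft(op$gamma * stats::fft(s), inverse = TRUE) / length(s)
  if (!is.complex(s) && op$transfer_real) Re(out) else out
}

#' @rdname apply_Gamma
#' @export
adjoint_Gamma <- function(s, op) {
  if (inherits(s, "time_signal")) s <- s$samples
  out <- stats::fft(Conj(op$gamma) * stats::fft(s), inverse = TRUE) / length(s)
  if (!is.complex(s) && op$transfer_real) Re(out) else out
}

#' @rdname apply_Gamma
#' @return `gamma_transfer`: the complex diagonal of the transfer function
#'   over all FFT bins (zero inside the notch).
#' @export
gamma_transfer <- function(op) op$gamma

#' Harmonic band selection S
#'
#' Extracts the Fourier coefficients in the retained bands `k = 2..K` from a
#' full-length spectrum; the fundamental is excluded (it is removed by the
#' notch filter anyway). `harmonic_scatter` is the adjoint: it places the
#' coefficients back into an otherwise-zero spectrum, so that
#' `S S^H = I` on the compressed space.
#'
#' @param spectrum Complex vector of length `op$n_time` (an unnormalized FFT
#'   of the signal).
#' @param op An [mpi_operator()] built with compression enabled.
#' @param drive_axis,angle Tags stored on the resulting block.
#' @return `harmonic_select`: a [harmonic_block()].
#'   `harmonic_scatter`: a complex spectrum of length `op$n_time`.
#' @export
harmonic_select <- function(spectrum, op, drive_axis = op$model$drive_axis,
                            angle = 0) {
  stopifnot(length(spectrum) == op$n_time)
  if (is.null(op$bands)) {
    return(harmonic_block(spectrum, list(full = seq_len(op$n_time)),
                          K = NULL, bandwidth = Inf,
                          f0 = op$model$drive_frequency,
                          sample_rate = op$model$sample_rate,
                          n_time = op$n_time,
                          drive_axis = drive_axis, angle = angle))
  }
  harmonic_block(spectrum[unlist(op$bands)], op$bands,
                 K = op$K, bandwidth = op$bandwidth,
                 f0 = op$model$drive_frequency,
                 sample_rate = op$model$sample_rate, n_time = op$n_time,
                 drive_axis = drive_axis, angle = angle)
}

#' @rdname harmonic_select
#' @param block A [harmonic_block()].
#' @export
harmonic_scatter <- function(block, op) {
  z <- complex(op$n_time)
  z[unlist(block$band_index_map)] <- block$coefficients
  z
}

#' Complete time-domain forward model M = Gamma V E H B
#'
#' Maps an in-plane density to the notch-filtered received signal.
#'
#' @param rho In-plane density (matrix or vector).
#' @param op An [mpi_operator()].
#' @param drive_axis,angle Tags for the returned signal.
#' @return `apply_M`: a [time_signal()]. `adjoint_M`: an image (complex if
#'   the input signal is complex).
#' @export
apply_M <- function(rho, op, drive_axis = op$model$drive_axis, angle = 0) {
  s0 <- apply_V(apply_E(apply_H(apply_B(rho, op), op), op), op)
  time_signal(apply_Gamma(s0, op), op$model$sample_rate, drive_axis, angle)
}

#' @rdname apply_M
#' @param s A [time_signal()] or plain signal vector.
#' @export
adjoint_M <- function(s, op) {
  if (inherits(s, "time_signal")) s <- s$samples
  .adjoint_VEHB(adjoint_Gamma(s, op), op)
}

#' Compressed forward model A_DC = S D_Gamma F V E H B
#'
#' The harmonic-domain forward operator: raw signal, one forward FFT,
#' transfer-function multiplication, band selection. `method =
#' "filter_then_fft"` evaluates the algebraically identical composition
#' `S F Gamma V E H B` (filter in the time domain, then transform), which
#' costs three FFTs; it exists as the reference for the equivalence of the
#' two formulations.
#'
#' @param rho In-plane density (matrix or vector).
#' @param op An [mpi_operator()].
#' @param method `"single_fft"` (default) or `"filter_then_fft"`.
#' @param drive_axis,angle Tags for the returned block.
#' @return `apply_ADC`: a [harmonic_block()]. `adjoint_ADC`: a complex image.
#' @export
apply_ADC <- function(rho, op, method = c("single_fft", "filter_then_fft"),
                      drive_axis = op$model$drive_axis, angle = 0) {
  method <- match.arg(method)
  if (method == "single_fft") {
    s0 <- apply_V(apply_E(apply_H(apply_B(rho, op), op), op), op)
    spec <- op$gamma * stats::fft(s0)
  } else {
    spec <- stats::fft(apply_M(rho, op)$samples)
  }
  harmonic_select(spec, op, drive_axis = drive_axis, angle = angle)
}

#' @rdname apply_ADC
#' @param block A [harmonic_block()] (or complex coefficient vector laid out
#'   like one).
#' @export
adjoint_ADC <- function(block, op) {
  if (inherits(block, "harmonic_block")) {
    z <- harmonic_scatter(block, op)
  } else {
    idx <- if (is.null(op$bands)) seq_len(op$n_time) else unlist(op$bands)
    stopifnot(length(block) == length(idx))
    z <- complex(op$n_time)
    z[idx] <- block
  }
  s <- stats::fft(Conj(op$gamma) * z, inverse = TRUE)
  .adjoint_VEHB(s, op)
}

#' Harmonic-band energy retention of a signal
#'
#' Fraction of the notch-filtered signal energy that falls inside the
#' retained harmonic bands (mirror bins of the real signal's conjugate-
#' symmetric spectrum are counted on both sides, so the fraction matches the
#' one-sided accounting).
#'
#' @param s A [time_signal()] or signal vector.
#' @param op An [mpi_operator()] with compression enabled.
#' @return Scalar in `[0, 1]`.
#' @export
harmonic_energy_retention <- function(s, op) {
  if (inherits(s, "time_signal")) s <- s$samples
  stopifnot(!is.null(op$bands))
  spec <- op$gamma * stats::fft(s)
  n <- length(spec)
  bins <- unlist(op$bands)
  mirror <- ((n + 1 - bins) %% n) + 1
  keep <- union(bins, mirror)
  sum(Mod(spec[keep])^2) / sum(Mod(spec)^2)
}
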