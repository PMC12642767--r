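# Discrete operator chain: component behavior, oracles, adjoints.

test_that("receive-sensitivity weighting B picks the drive axis", {
  op <- tiny_op()
  rho <- matrix(rnorm(256), 16, 16)
  w <- apply_B(rho, op)
  expect_equal(w$z, rho)
  expect_true(all(w$x == 0) && all(w$y == 0))
  z <- apply_B(matrix(0, 16, 16), op)
  expect_true(all(unlist(z) == 0))
  expect_lt(dot_test(function(x) unlist(apply_B(matrix(x, 16, 16), op)),
                     function(y) as.vector(adjoint_B(
                       list(x = matrix(y[1:256], 16, 16),
                            y = matrix(y[257:512], 16, 16),
                            z = matrix(y[513:768], 16, 16)), op)),
                     256, 768), 1e-12)
})

test_that("PSF convolution H matches a delta identity and a spatial-domain oracle", {
  op <- tiny_op()
  g <- op$grid
  xs <- grid_axis(g, 1); zs <- grid_axis(g, 2)
  d <- matrix(0, 16, 16); d[6, 11] <- 1
  C <- apply_H(list(x = matrix(0, 16, 16), y = matrix(0, 16, 16), z = d), op)
  hexp <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    hexp[i, j] <- psf_tensor(op$model, op$particle,
                             c(xs[i] - xs[6], 0, zs[j] - zs[11]))[3, 3] * op$cell
  }
  expect_lt(max(abs(C$z$z - hexp)), 1e-12 * max(abs(hexp)))
  expect_true(all(C$y$y == 0) && all(C$z$y == 0) && all(C$y$z == 0))

  # brute-force O(N^2) spatial convolution on an 8x8 grid
  op8 <- tiny_op(8)
  set.seed(7)
  img <- matrix(rnorm(64), 8, 8)
  C8 <- apply_H(list(x = matrix(0, 8, 8), y = matrix(0, 8, 8), z = img), op8)
  xs8 <- grid_axis(op8$grid, 1); zs8 <- grid_axis(op8$grid, 2)
  ref <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    acc <- 0
    for (p in 1:8) for (q in 1:8) {
      acc <- acc + img[p, q] * psf_tensor(op8$model, op8$particle,
        c(xs8[i] - xs8[p], 0, zs8[j] - zs8[q]))[3, 3]
    }
    ref[i, j] <- acc * op8$cell
  }
  expect_lt(rel_l2(C8$z$z, ref), 1e-10)
})

test_that("trajectory sampling E interpolates constants exactly", {
  op <- tiny_op()
  cimg <- matrix(3.7, 16, 16)
  Czz <- list(x = list(x = matrix(0, 16, 16), y = matrix(0, 16, 16), z = matrix(0, 16, 16)),
              y = list(x = matrix(0, 16, 16), y = matrix(0, 16, 16), z = matrix(0, 16, 16)),
              z = list(x = matrix(0, 16, 16), y = matrix(0, 16, 16), z = cimg))
  s <- apply_E(Czz, op)
  expect_equal(s$z$z, rep(3.7, op$n_time), tolerance = 1e-12)
})

test_that("velocity operator V is linear in the magnetic moment", {
  op <- tiny_op()
  rho <- matrix(rexp(256), 16, 16)
  s1 <- apply_M(rho, op)$samples
  op2 <- tiny_op()
  op2$particle$m <- 2 * op2$particle$m
  # kernels do not depend on m; doubling m doubles the signal
  s2 <- apply_V(apply_E(apply_H(apply_B(rho, op2), op2), op2), op2)
  s2 <- apply_Gamma(s2, op2)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("notch filter kills the fundamental and passes other harmonics", {
  op <- tiny_op()
  t <- scan_times(op$model)
  f0 <- op$model$drive_frequency
  tone1 <- sin(2 * pi * f0 * t)
  expect_lt(max(abs(apply_Gamma(tone1, op))), 1e-12)
  tone3 <- cos(2 * pi * 3 * f0 * t)
  expect_equal(apply_Gamma(tone3, op), tone3, tolerance = 1e-12)
})

test_that("harmonic band selection matches a bin-enumeration oracle", {
  op <- tiny_op()
  n <- op$n_time
  fs <- op$model$sample_rate; f0 <- op$model$drive_frequency
  f <- (seq_len(n) - 1) * fs / n
  # independent bin-by-bin count over positive frequencies
  for (k in 2:5) {
    expected <- sum(abs(f - k * f0) <= 250 & seq_len(n) <= floor(n / 2) + 1)
    expect_identical(length(op$bands[[paste0("k", k)]]), as.integer(expected))
  }
  # energy at 2.2 f0 is in-band when the bandwidth covers it; at f0 nothing
  # is kept (k starts at 2)
  opw <- tiny_op(bandwidth = 2e4)  # +/- 10 kHz bands cover 2.2 f0
  t <- scan_times(op$model)
  # use an exact FFT bin near 2.2 f0 so all its energy sits in one bin
  target_bin <- which.min(abs(f - 2.2 * f0))
  sig <- cos(2 * pi * f[target_bin] * t)
  blk <- harmonic_select(stats::fft(sig), opw)
  expect_gt(sum(Mod(blk$coefficients)^2), 0.99 * sum(Mod(stats::fft(sig))^2) / 2)
  blk0 <- harmonic_select(stats::fft(sin(2 * pi * f0 * t)), opw)
  expect_lt(sum(Mod(blk0$coefficients)^2), 1e-12 * n)
  # S S^H = identity on the compressed space
  nb <- length(unlist(op$bands))
  z <- complex(real = rnorm(nb), imaginary = rnorm(nb))
  blkz <- harmonic_block(z, op$bands, op$K, op$bandwidth, f0, fs, n)
  expect_identical(harmonic_select(harmonic_scatter(blkz, op), op)$coefficients, z)
})

test_that("compression accounting is exact", {
  op <- tiny_op()
  blk <- apply_ADC(matrix(rnorm(256), 16, 16), op)
  acc <- compression_ratio(blk)
  expect_identical(acc$ratio,
                   (length(blk$coefficients) * 16) / (op$n_time * 8))
})

test_that("forward model M is linear and vanishes on zero input", {
  op <- tiny_op()
  expect_true(all(apply_M(matrix(0, 16, 16), op)$samples == 0))
  set.seed(11)
  r1 <- matrix(rnorm(256), 16, 16); r2 <- matrix(rnorm(256), 16, 16)
  s12 <- apply_M(r1 + r2, op)$samples
  expect_lt(rel_l2(s12, apply_M(r1, op)$samples + apply_M(r2, op)$samples), 1e-10)
  a <- 3.25
  expect_equal(apply_M(a * r1, op)$samples, a * apply_M(r1, op)$samples,
               tolerance = 1e-12)
})

test_that("single-FFT compressed operator equals the filter-then-FFT form", {
  op <- tiny_op()
  set.seed(12)
  rho <- matrix(rnorm(256), 16, 16)
  b13 <- apply_ADC(rho, op)$coefficients
  b12 <- apply_ADC(rho, op, method = "filter_then_fft")$coefficients
  expect_lt(rel_l2(b13, b12), 1e-10)
  expect_true(all(apply_ADC(matrix(0, 16, 16), op)$coefficients == 0))
})

test_that("operator components pass randomized adjoint dot-tests", {
  op <- tiny_op()
  n <- op$n_time
  nb <- length(unlist(op$bands))
  # H on the (z, {x,z}) block
  errH <- dot_test(
    function(x) {
      C <- apply_H(list(x = matrix(0, 16, 16), y = matrix(0, 16, 16),
                        z = matrix(x, 16, 16)), op)
      c(as.vector(C$z$x), as.vector(C$z$z))
    },
    function(y) {
      C0 <- lapply(1:3, function(i) list(x = matrix(0, 16, 16),
                                         y = matrix(0, 16, 16),
                                         z = matrix(0, 16, 16)))
      names(C0) <- c("x", "y", "z")
      C0$z$x <- matrix(y[1:256], 16, 16)
      C0$z$z <- matrix(y[257:512], 16, 16)
      as.vector(adjoint_H(C0, op)$z)
    }, 256, 512)
  expect_lt(errH, 1e-10)
  # E on one series
  errE <- dot_test(
    function(x) as.vector(fflmpi:::.spmul(op$E, x)),
    function(y) as.vector(fflmpi:::.spmul(op$Et, y)),
    256, n)
  expect_lt(errE, 1e-12)
  # Gamma with complex inputs (conjugate transfer adjoint)
  errG <- dot_test(function(x) apply_Gamma(x, op),
                   function(y) adjoint_Gamma(y, op),
                   n, n, complex_in = TRUE, complex_out = TRUE)
  expect_lt(errG, 1e-12)
  # full compressed composite, complex inner product
  errA <- dot_test(
    function(x) apply_ADC(matrix(x, 16, 16), op)$coefficients,
    function(y) as.vector(adjoint_ADC(
      harmonic_block(y, op$bands, op$K, op$bandwidth,
                     op$model$drive_frequency, op$model$sample_rate, n), op)),
    256, nb, complex_out = TRUE)
  expect_lt(errA, 1e-8)
})

test_that("harmonic bands retain nearly all notch-filtered energy of a scan", {
  # default scan configuration (slow raster, 8 lines): the raster's
  # modulation sidebands stay well inside the half-kHz bands
  g <- image_grid(c(24, 24), 1.5e-4)
  op <- mpi_operator(g, scanner_model(), particle_model())
  xs <- grid_axis(g, 1); zs <- grid_axis(g, 2)
  rho <- outer(xs, zs, function(x, z) exp(-(x^2 + z^2) / (2 * (3e-4)^2)))
  s <- apply_M(rho, op)
  expect_gt(harmonic_energy_retention(s, op), 0.95)
})

test_that("Nyquist and band-overlap violations are rejected", {
  g <- tiny_grid()
  sm <- tiny_scanner()
  expect_error(mpi_operator(g, sm, particle_model(), K = 6),
               "Nyquist")
  expect_error(mpi_operator(g, sm, particle_model(), K = 3, bandwidth = 5e4),
               "overlap")
})
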