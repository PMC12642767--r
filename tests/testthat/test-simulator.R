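# Phantoms, seeded scan simulation, detection-limit analysis.

test_that("point-source phantoms deposit the requested mass", {
  g <- image_grid(c(24, 24, 24), 1.5e-4)
  # at the isocenter of an even grid the source splits over 8 voxels
  ph <- make_phantom(phantom_spec("point_sources",
                                  positions = c(0, 0, 0), amplitudes = 1), g)
  expect_equal(sum(ph), 1, tolerance = 1e-12)
  expect_identical(sum(ph > 0), 8L)
  # multiple sources with distinct amplitudes
  ph3 <- make_phantom(phantom_spec("point_sources",
                                   positions = rbind(c(-9e-4, -6e-4, 6e-4),
                                                     c(6.75e-4, 4.5e-4, -4.5e-4),
                                                     c(-0.75e-4, -9e-4, 0.75e-4)),
                                   amplitudes = c(1, 5, 50)), g)
  expect_equal(sum(ph3), 56, tolerance = 1e-12)
  expect_true(all(ph3 >= 0))
  # empty spec gives a zero volume; out-of-grid support errors
  expect_true(all(make_phantom(phantom_spec("point_sources",
                                            positions = matrix(0, 0, 3)), g) == 0))
  expect_error(make_phantom(phantom_spec("point_sources",
                                         positions = c(0, 0, 1)), g),
               "fit inside")
})

test_that("tube phantoms match the analytic sample volume", {
  # 167 uL vial emulated as a cylinder: r = 4 mm, height such that
  # pi r^2 h = 167e-9 m^3
  r <- 4e-3
  h <- 167e-9 / (pi * r^2)
  g <- image_grid(c(32, 32, 32), 4e-4)
  ph <- make_phantom(phantom_spec("tubes", positions = c(0, 0, 0),
                                  radius = r, height = h, axis = "z"), g)
  expect_equal(sum(ph) * prod(g$spacing), 167e-9, tolerance = 5e-3)
})

test_that("scan simulation is seeded, reproducible, and exact when noise-free", {
  st <- tiny_study3d(n = 12, n_angles = 2)
  vol <- make_phantom(phantom_spec("point_sources",
                                   positions = rbind(c(-4e-4, 2e-4, 3e-4),
                                                     c(3e-4, -3e-4, -2e-4)),
                                   amplitudes = c(1, 3)), st$grid)
  clean <- simulate_scan(vol, st$m3)
  expect_identical(clean$b, forward_A(vol, st$m3))
  zero <- simulate_scan(array(0, dim(vol)), st$m3)
  expect_true(all(zero$b == 0))
  n1 <- simulate_scan(vol, st$m3, noise_snr_db = 20, seed = 7)
  n2 <- simulate_scan(vol, st$m3, noise_snr_db = 20, seed = 7)
  n3 <- simulate_scan(vol, st$m3, noise_snr_db = 20, seed = 8)
  expect_identical(n1$b, n2$b)
  expect_false(identical(n1$b, n3$b))
})

test_that("injected noise realizes the requested SNR", {
  st <- tiny_study3d(n = 12, n_angles = 1)
  vol <- make_phantom(phantom_spec("point_sources",
                                   positions = c(0, 0, 0), amplitudes = 1),
                      st$grid)
  clean <- simulate_scan(vol, st$m3, return_raw = TRUE)
  snrs <- vapply(1:10, function(sd) {
    noisy <- simulate_scan(vol, st$m3, noise_snr_db = 20, seed = sd,
                           return_raw = TRUE)
    err <- vapply(seq_along(noisy$signals), function(i) {
      op <- st$m3$ops[[noisy$signals[[i]]$drive_axis]]
      noise <- noisy$signals[[i]]$samples - clean$signals[[i]]$samples
      sig <- apply_Gamma(clean$signals[[i]]$samples, op)
      10 * log10(mean(sig^2) / mean(noise^2))
    }, numeric(1))
    mean(err)
  }, numeric(1))
  expect_true(all(abs(snrs - 20) < 0.5))
})

test_that("detection limit analysis solves the closed-form crossing", {
  # image values = 2 * mass in the ROI voxel, void regions constant 0.1:
  # the 3x noise threshold (0.3) crosses the fit at mass 0.15
  g <- c(10, 10, 10)
  masses <- c(5, 10, 50)
  mkvol <- function(mass) {
    v <- array(0, g)
    v[2, 2, 2] <- 2 * mass
    v[6:8, 6:8, 6:8] <- 0.1
    v
  }
  rois <- rep(list(rbind(c(2, 2), c(2, 2), c(2, 2))), 3)
  voids <- list(rbind(c(6, 6), c(6, 8), c(6, 8)),
                rbind(c(7, 7), c(6, 8), c(6, 8)),
                rbind(c(8, 8), c(6, 8), c(6, 8)),
                rbind(c(6, 8), c(6, 6), c(7, 8)),
                rbind(c(6, 8), c(7, 8), c(6, 6)))
  res <- sensitivity_analysis(lapply(masses, mkvol), masses, rois, voids)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_equal(res$noise, 0.1, tolerance = 1e-12)
  expect_equal(res$threshold, 0.3, tolerance = 1e-12)
  expect_equal(res$detection_limit, 0.15, tolerance = 1e-12)
  expect_false(res$flag)
})

test_that("degenerate sensitivity inputs are flagged or rejected", {
  g <- c(8, 8, 8)
  zero <- array(0, g)
  rois <- rep(list(rbind(c(1, 2), c(1, 2), c(1, 2))), 3)
  voids <- list(rbind(c(6, 8), c(6, 8), c(6, 8)))
  res <- sensitivity_analysis(rep(list(zero), 3), c(1, 2, 3), rois, voids)
  expect_true(res$flag)
  expect_true(is.na(res$detection_limit))
  expect_error(sensitivity_analysis(rep(list(zero), 2), c(2, 2),
                                    rois[1:2], voids), "distinct")
  # overlapping void / ROI boxes are rejected
  expect_error(sensitivity_analysis(rep(list(zero), 3), c(1, 2, 3), rois,
                                    list(rbind(c(1, 3), c(1, 3), c(1, 3)))),
               "disjoint")
})

test_that("sensitivity fit recovers a generative slope under noise", {
  # synthetic series: ROI value = slope * mass + gaussian noise at 30 dB
  # relative to the mid-series signal, 10 seeds
  slope_true <- 2.5
  masses <- c(1, 2, 5, 10, 20)
  g <- c(12, 12, 12)
  rois <- rep(list(rbind(c(3, 4), c(3, 4), c(3, 4))), length(masses))
  voids <- list(rbind(c(9, 11), c(9, 11), c(1, 3)),
                rbind(c(9, 11), c(1, 3), c(9, 11)),
                rbind(c(1, 3), c(9, 11), c(9, 11)),
                rbind(c(9, 11), c(9, 11), c(9, 11)),
                rbind(c(1, 3), c(1, 3), c(9, 11)))
  slopes <- vapply(1:10, function(sd) {
    set.seed(sd)
    sig_ref <- slope_true * stats::median(masses)
    sigma <- sig_ref / sqrt(10^(30 / 10)) / sqrt(8)  # ROI has 8 voxels
    vols <- lapply(masses, function(m) {
      v <- array(stats::rnorm(prod(g), sd = sigma), g)
      v[3:4, 3:4, 3:4] <- v[3:4, 3:4, 3:4] + slope_true * m / 8
      v
    })
    sensitivity_analysis(vols, masses, rois, voids)$slope
  }, numeric(1))
  expect_true(all(abs(slopes - slope_true) / slope_true < 0.05))
})

test_that("find_peaks locates separated local maxima in order", {
  v <- array(0, c(10, 10, 10))
  v[3, 3, 3] <- 5; v[8, 2, 6] <- 50; v[5, 8, 8] <- 1
  pk <- find_peaks(v, 3)
  expect_equal(unlist(pk[1, 1:3], use.names = FALSE), c(8, 2, 6))
  expect_equal(unlist(pk[2, 1:3], use.names = FALSE), c(3, 3, 3))
  expect_equal(pk$value, c(50, 5, 1))
})
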