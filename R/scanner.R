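#' Scanner description for a field-free-line MPI system
#'
#' Bundles the static gradient, the sinusoidal drive field, the slow zig-zag
#' raster, and the receive chain of an FFL scanner. The gradient matrix is
#' `diag(-G0, 0, G0)`: its null middle row/column is what makes the field-free
#' locus a *line* along the y-axis rather than a point. All magnetic
#' quantities are stored as \eqn{\mu_0 H} in tesla, so the Langevin saturation
#' constant `beta` of [particle_model()] carries units 1/T.
#'
#' Defaults describe a desk-scale scan with the physics of a preclinical FFL
#' scanner: 5.7 T/m gradient, 45 kHz drive at 5 mT amplitude, and a slow
#' zig-zag raster (fast triangle sweep along x, slow linear shift along z).
#' The default field of view is small (3.6 mm per axis) so that the intrinsic
#' resolution \eqn{1/(\beta G_0)} is a realistic fraction of the FOV at mesh
#' sizes that simulate quickly; all parameters scale linearly.
#'
#' @param G0 Gradient strength, T/m. Must be > 0.
#' @param drive_amplitude Drive field amplitude (\eqn{\mu_0 H}), tesla.
#' @param drive_frequency Fundamental drive frequency \eqn{f_0}, Hz.
#' @param drive_axis `"z"` or `"x"`; the FFL axis is always y.
#' @param fov Named or unnamed length-3 numeric, field-of-view extents (m)
#'   along x, y, z.
#' @param raster List with `n_lines` (fast lines per scan), `line_period`
#'   (s per fast line), `x_amplitude` (m, half-extent of the fast triangle
#'   sweep), `z_extent` (m, half-extent of the slow linear shift). Defaults
#'   are derived from `fov`: the fast sweep covers the x FOV, the slow shift
#'   covers the z FOV minus the drive excursion.
#' @param sample_rate Receive sampling rate, Hz. Must satisfy the Nyquist
#'   condition for every retained harmonic (checked again when harmonic bands
#'   are constructed).
#' @param notch_halfwidth Half-width (Hz) of the receive-chain notch filter
#'   that removes the fundamental at \eqn{f_0}.
#' @param receive_sensitivity Either the string `"drive"` (homogeneous unit
#'   sensitivity along the drive axis, the default) or a length-3 numeric
#'   vector giving a homogeneous sensitivity direction.
#' @return An object of class `scanner_model`.
#' @examples
#' sm <- scanner_model()
#' sm$G0 * ffl_position(sm, 1 / (4 * sm$drive_frequency))  # peak drive field
#' @export
scanner_model <- function(G0 = 5.7,
                          drive_amplitude = 5e-3,
                          drive_frequency = 45e3,
                          drive_axis = c("z", "x"),
                          fov = c(x = 3.6e-3, y = 3.6e-3, z = 3.6e-3),
                          raster = NULL,
                          sample_rate = 480e3,
                          notch_halfwidth = 1e3,
                          receive_sensitivity = "drive") {
  drive_axis <- match.arg(drive_axis)
  stopifnot(G0 > 0, drive_amplitude > 0, drive_frequency > 0,
            sample_rate > 2 * drive_frequency, notch_halfwidth >= 0)
  fov <- as.numeric(fov)
  stopifnot(length(fov) == 3, all(fov > 0))
  names(fov) <- c("x", "y", "z")
  excursion <- drive_amplitude / G0
  if (is.null(raster)) {
    raster <- list(n_lines = 8L, line_period = 0.05,
                   x_amplitude = fov[["x"]] / 2,
                   z_extent = max(0, fov[["z"]] / 2 - excursion))
  }
  stopifnot(raster$n_lines >= 1, raster$line_period > 0,
            raster$x_amplitude >= 0, raster$z_extent >= 0)
  if (identical(receive_sensitivity, "drive")) {
    b <- c(x = 0, y = 0, z = 0)
    b[drive_axis] <- 1
  } else {
    b <- as.numeric(receive_sensitivity)
    stopifnot(length(b) == 3, all(is.finite(b)))
    names(b) <- c("x", "y", "z")
  }
  structure(list(
    G0 = G0,
    drive_amplitude = drive_amplitude,
    drive_frequency = drive_frequency,
    drive_axis = drive_axis,
    ffl_axis = "y",
    fov = fov,
    raster = raster[c("n_lines", "line_period", "x_amplitude", "z_extent")],
    sample_rate = sample_rate,
    notch_halfwidth = notch_halfwidth,
    receive_sensitivity = b
  ), class = "scanner_model")
}

#' Magnetic nanoparticle ensemble parameters
#'
#' The Langevin model reduces the tracer to two constants: the magnetic
#' moment `m` of a single particle and a conglomerate saturation constant
#' `beta` which converts field strength (\eqn{\mu_0 H}, tesla) into the
#' dimensionless Langevin argument. `1/beta` is the field scale at which the
#' particles saturate, and \eqn{1/(\beta G_0)} is the intrinsic spatial
#' resolution of the scanner. Defaults emulate a multi-core iron-oxide tracer
#' saturating at a couple of mT.
#'
#' @param m Magnetic moment of one particle, A m^2.
#' @param beta Langevin saturation constant, 1/T (applied to \eqn{\mu_0 H}).
#' @return An object of class `particle_model`.
#' @export
particle_model <- function(m = 1e-18, beta = 600) {
  stopifnot(m > 0, beta > 0)
  structure(list(m = m, beta = beta), class = "particle_model")
}

#' @export
print.scanner_model <- function(x, ...) {
  cat("<scanner_model>\n")
  cat(sprintf("  gradient      %.3g T/m (FFL along %s)\n", x$G0, x$ffl_axis))
  cat(sprintf("  drive         %.3g mT @ %.3g kHz along %s (excursion %.3g mm)\n",
              1e3 * x$drive_amplitude, 1e-3 * x$drive_frequency, x$drive_axis,
              1e3 * x$drive_amplitude / x$G0))
  cat(sprintf("  raster        %d lines x %.3g ms, x +/- %.3g mm, z +/- %.3g mm\n",
              x$raster$n_lines, 1e3 * x$raster$line_period,
              1e3 * x$raster$x_amplitude, 1e3 * x$raster$z_extent))
  cat(sprintf("  fov           %.3g x %.3g x %.3g mm\n",
              1e3 * x$fov[["x"]], 1e3 * x$fov[["y"]], 1e3 * x$fov[["z"]]))
  cat(sprintf("  sampling      %.4g kHz, notch +/- %.3g Hz at f0\n",
              1e-3 * x$sample_rate, x$notch_halfwidth))
  invisible(x)
}

#' @export
print.particle_model <- function(x, ...) {
  cat(sprintf("<particle_model> m = %.3g A m^2, beta = %.3g 1/T (saturation ~%.3g mT)\n",
              x$m, x$beta, 1e3 / x$beta))
  invisible(x)
}

#' Scan duration and sample times
#'
#' The scan lasts `n_lines * line_period` seconds; samples are taken at
#' `t_k = (k - 1) / sample_rate`.
#'
#' @param model A [scanner_model()].
#' @return `scan_duration`: duration in seconds. `scan_times`: vector of
#'   sample times covering one scan.
#' @export
scan_duration <- function(model) {
  model$raster$n_lines * model$raster$line_period
}

#' @rdname scan_duration
#' @export
scan_times <- function(model) {
  n <- round(scan_duration(model) * model$sample_rate)
  seq(0, by = 1 / model$sample_rate, length.out = n)
}

.check_scan_time <- function(model, t) {
  if (any(t < 0 | t > scan_duration(model))) {
    stop("time outside scan duration [0, ", scan_duration(model), "] s",
         call. = FALSE)
  }
}

# Slow raster position (x, z) and velocity at times t. Fast triangle sweep in
# x with alternating direction per line; slow linear ramp in z across the
# whole scan. Velocity at triangle vertices is the right-hand derivative.
.raster_position <- function(model, t) {
  r <- model$raster
  Tl <- r$line_period
  i <- pmin(floor(t / Tl), r$n_lines - 1)
  u <- t / Tl - i
  dir <- ifelse(i %% 2 == 0, 1, -1)
  x <- r$x_amplitude * (2 * u - 1) * dir
  dur <- scan_duration(model)
  z <- if (r$z_extent > 0) r$z_extent * (2 * t / dur - 1) else rep(0, length(t))
  vx <- dir * 2 * r$x_amplitude / Tl
  vz <- rep(if (r$z_extent > 0) 2 * r$z_extent / dur else 0, length(t))
  list(x = x, z = z, vx = vx, vz = vz)
}

#' Drive plus raster field
#'
#' The total homogeneous excitation \eqn{H_D(t)}: a sinusoid of amplitude `A`
#' at `f0` along the drive axis plus the slow shift fields that implement the
#' raster. It has no y-component, so the FFL sweeps within xz planes.
#'
#' @param model A [scanner_model()].
#' @param t Vector of times (s) within the scan.
#' @return `length(t)` x 3 matrix of field components (T), columns x, y, z.
#' @export
drive_field <- function(model, t) {
  .check_scan_time(model, t)
  ras <- .raster_position(model, t)
  H <- matrix(0, length(t), 3, dimnames = list(NULL, c("x", "y", "z")))
  s <- model$drive_amplitude * sin(2 * pi * model$drive_frequency * t)
  if (model$drive_axis == "z") {
    H[, "z"] <- s
  } else {
    H[, "x"] <- -s
  }
  # raster fields chosen so the FFL raster position is (+x_r, +z_r)
  H[, "x"] <- H[, "x"] - model$G0 * ras$x
  H[, "z"] <- H[, "z"] + model$G0 * ras$z
  H
}

#' Total magnetic field at a point
#'
#' \eqn{H(x, t) = H_D(t) - G x} with `G = diag(-G0, 0, G0)`. Vanishes on the
#' field-free line \eqn{\{\xi(t) + s \hat y\}} and grows linearly with the
#' in-plane offset from it.
#'
#' @param model A [scanner_model()].
#' @param x Length-3 position (m).
#' @param t Vector of times (s) within the scan.
#' @return `length(t)` x 3 matrix (T); the y column is identically 0.
#' @export
magnetic_field <- function(model, x, t) {
  stopifnot(length(x) == 3)
  H <- drive_field(model, t)
  H[, "x"] <- H[, "x"] + model$G0 * x[1]
  H[, "z"] <- H[, "z"] - model$G0 * x[3]
  H
}

#' Field-free line position and velocity
#'
#' The FFL is the line \eqn{H(x,t) = 0}; its in-plane trace is
#' \eqn{\xi_x = -H_{D,x}/G_0}, \eqn{\xi_z = +H_{D,z}/G_0}. For a pure z-axis
#' drive with no raster this is \eqn{(0, (A/G_0)\sin 2\pi f_0 t)}.
#' `ffl_velocity` is the analytic time derivative (drive sinusoid
#' differentiated in closed form; triangle raster uses the right-hand slope
#' at line turn-points).
#'
#' @param model A [scanner_model()].
#' @param t Vector of times (s) within the scan.
#' @return `length(t)` x 2 matrix with columns x, z: meters for
#'   `ffl_position`, m/s for `ffl_velocity`.
#' @export
ffl_position <- function(model, t) {
  .check_scan_time(model, t)
  ras <- .raster_position(model, t)
  s <- (model$drive_amplitude / model$G0) *
    sin(2 * pi * model$drive_frequency * t)
  if (model$drive_axis == "z") {
    cbind(x = ras$x, z = s + ras$z)
  } else {
    cbind(x = -s + ras$x, z = ras$z)
  }
}

#' @rdname ffl_position
#' @export
ffl_velocity <- function(model, t) {
  .check_scan_time(model, t)
  ras <- .raster_position(model, t)
  w <- 2 * pi * model$drive_frequency
  ds <- (model$drive_amplitude / model$G0) * w * cos(w * t)
  if (model$drive_axis == "z") {
    cbind(x = ras$vx, z = ds + ras$vz)
  } else {
    cbind(x = -ds + ras$vx, z = ras$vz)
  }
}
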