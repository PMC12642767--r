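#' Uniformly sampled time-domain MPI signal
#'
#' @param samples Numeric (or complex, for intermediate adjoint quantities)
#'   vector of signal samples.
#' @param sample_rate Sampling rate, Hz.
#' @param drive_axis Drive axis tag, `"x"` or `"z"`.
#' @param angle Projection angle tag, degrees.
#' @return An object of class `time_signal`.
#' @export
time_signal <- function(samples, sample_rate, drive_axis = "z", angle = 0) {
  stopifnot(all(is.finite(Re(samples))), sample_rate > 0)
  structure(list(samples = samples, sample_rate = sample_rate,
                 drive_axis = drive_axis, angle = angle),
            class = "time_signal")
}

#' @export
print.time_signal <- function(x, ...) {
  cat(sprintf(
    "<time_signal> %d samples @ %.4g kHz (%.4g ms), drive %s, angle %g deg\n",
    length(x$samples), 1e-3 * x$sample_rate,
    1e3 * length(x$samples) / x$sample_rate, x$drive_axis, x$angle))
  invisible(x)
}

#' Harmonic-band compressed signal data
#'
#' Complex Fourier coefficients in narrow bands around the drive-frequency
#' harmonics `k = 2..K` (one-sided: positive-frequency bins only). This is
#' the compressed data vector that the reconstruction consumes; keeping a few
#' hundred bins out of hundreds of thousands of samples is what makes the
#' full multi-angle 3D inversion tractable.
#'
#' @param coefficients Complex vector, concatenated bands in increasing `k`.
#' @param band_index_map Named list: FFT bin indices (1-based, into the
#'   length-`n_time` spectrum) per harmonic.
#' @param K Highest retained harmonic.
#' @param bandwidth Total bandwidth per harmonic band, Hz.
#' @param f0 Fundamental drive frequency, Hz.
#' @param sample_rate Original sampling rate, Hz.
#' @param n_time Original number of time samples.
#' @param drive_axis,angle Acquisition tags, as in [time_signal()].
#' @return An object of class `harmonic_block`.
#' @export
harmonic_block <- function(coefficients, band_index_map, K, bandwidth, f0,
                           sample_rate, n_time, drive_axis = "z", angle = 0) {
  stopifnot(length(coefficients) == length(unlist(band_index_map)))
  structure(list(coefficients = as.complex(coefficients),
                 band_index_map = band_index_map,
                 K = K, bandwidth = bandwidth, f0 = f0,
                 sample_rate = sample_rate, n_time = as.integer(n_time),
                 drive_axis = drive_axis, angle = angle),
            class = "harmonic_block")
}

#' @export
print.harmonic_block <- function(x, ...) {
  cat(sprintf(
    "<harmonic_block> %d bins (%s), K = %s, %.3g Hz/band, %d time samples, drive %s, angle %g deg\n",
    length(x$coefficients),
    paste(names(x$band_index_map), collapse = ", "),
    ifelse(is.null(x$K), "full spectrum", x$K),
    x$bandwidth, x$n_time, x$drive_axis, x$angle))
  invisible(x)
}

#' Compression accounting for a harmonic block
#'
#' Ratio of compressed to raw storage: retained bins times the width of a
#' complex double (16 bytes) over time samples times the width of a real
#' double (8 bytes).
#'
#' @param block A [harmonic_block()].
#' @return List with `n_bins`, `n_time`, `compressed_bytes`, `raw_bytes` and
#'   `ratio` (compressed / raw).
#' @export
compression_ratio <- function(block) {
  n_bins <- length(block$coefficients)
  compressed <- n_bins * 16
  raw <- block$n_time * 8
  list(n_bins = n_bins, n_time = block$n_time,
       compressed_bytes = compressed, raw_bytes = raw,
       ratio = compressed / raw)
}
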