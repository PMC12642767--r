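# Persistence: YAML configs with explicit unit suffixes, a schema-versioned
# container for signals / harmonic data, and NIfTI volumes.

.CONTAINER_SCHEMA <- "fflmpi-container"
.CONTAINER_VERSION <- 1L

#' Write / read scanner and particle configuration
#'
#' Serializes a [scanner_model()] and [particle_model()] to a YAML file.
#' Every quantity carries an explicit unit suffix in its key, so configs are
#' self-describing and unit mistakes surface at read time.
#'
#' @param model A [scanner_model()].
#' @param particle A [particle_model()].
#' @param path Output / input file path.
#' @return `read_config`: list with `model` and `particle`.
#' @export
write_config <- function(model, particle, path) {
  stopifnot(inherits(model, "scanner_model"), inherits(particle, "particle_model"))
  cfg <- list(
    scanner = list(
      gradient_T_per_m = model$G0,
      drive_amplitude_T = model$drive_amplitude,
      drive_frequency_Hz = model$drive_frequency,
      drive_axis = model$drive_axis,
      fov_m = as.list(model$fov),
      raster = list(n_lines = model$raster$n_lines,
                    line_period_s = model$raster$line_period,
                    x_amplitude_m = model$raster$x_amplitude,
                    z_extent_m = model$raster$z_extent),
      sample_rate_Hz = model$sample_rate,
      notch_halfwidth_Hz = model$notch_halfwidth,
      receive_sensitivity = as.list(model$receive_sensitivity)
    ),
    particle = list(moment_A_m2 = particle$m, beta_per_T = particle$beta)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- function(x, field) {
    if (is.null(x[[field]])) stop("config is missing required field '", field, "'")
    x[[field]]
  }
  sc <- need(cfg, "scanner"); pc <- need(cfg, "particle")
  ras <- need(sc, "raster")
  model <- scanner_model(
    G0 = need(sc, "gradient_T_per_m"),
    drive_amplitude = need(sc, "drive_amplitude_T"),
    drive_frequency = need(sc, "drive_frequency_Hz"),
    drive_axis = need(sc, "drive_axis"),
    fov = unlist(need(sc, "fov_m")),
    raster = list(n_lines = as.integer(need(ras, "n_lines")),
                  line_period = need(ras, "line_period_s"),
                  x_amplitude = need(ras, "x_amplitude_m"),
                  z_extent = need(ras, "z_extent_m")),
    sample_rate = need(sc, "sample_rate_Hz"),
    notch_halfwidth = need(sc, "notch_halfwidth_Hz"),
    receive_sensitivity = unlist(need(sc, "receive_sensitivity"))
  )
  particle <- particle_model(m = need(pc, "moment_A_m2"),
                             beta = need(pc, "beta_per_T"))
  list(model = model, particle = particle)
}

#' Write / read the signal container
#'
#' Persists time signals, harmonic blocks and arbitrary metadata in a
#' schema-versioned container with bit-exact round-trip. Compression
#' parameters (K, bandwidth, band layout) live inside each stored
#' [harmonic_block()], so a reconstruction cannot silently mismatch the
#' data's band layout. Unknown schema versions and structurally invalid
#' blocks are rejected with explicit errors before anything is returned.
#'
#' @param payload Named list; entries may include `signals` (list of
#'   [time_signal()]), `blocks` (list of [harmonic_block()]) and any
#'   metadata.
#' @param path File path (conventionally `.rds`).
#' @return `read_container`: the validated payload.
#' @export
write_container <- function(payload, path) {
  stopifnot(is.list(payload))
  obj <- list(schema = .CONTAINER_SCHEMA, version = .CONTAINER_VERSION,
              payload = payload)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$schema, .CONTAINER_SCHEMA)) {
    stop("not a ", .CONTAINER_SCHEMA, " file: ", path)
  }
  if (!identical(as.integer(obj$version), .CONTAINER_VERSION)) {
    stop("unsupported container schema version ", obj$version,
         " (supported: ", .CONTAINER_VERSION, ")")
  }
  for (blk in obj$payload$blocks) {
    for (field in c("coefficients", "band_index_map", "f0", "sample_rate",
                    "n_time")) {
      if (is.null(blk[[field]])) {
        stop("harmonic block in container is missing field '", field, "'")
      }
    }
  }
  obj$payload
}

#' Write / read a volume as NIfTI
#'
#' Volumes are written as double-precision NIfTI with the voxel spacing (in
#' mm, the format's conventional unit) in the header. Values round-trip
#' exactly; spacing round-trips at the header's float precision.
#'
#' @param vol 3D array.
#' @param grid The [image_grid()] the volume lives on.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `read_volume`: list with `volume` and `grid` (spacing recovered
#'   from the header, converted back to meters).
#' @export
write_volume <- function(vol, grid, path) {
  stopifnot(is.array(vol), length(dim(vol)) == 3, grid$dims == 3L)
  img <- RNifti::asNifti(vol * 1.0,
                         reference = list(pixdim = c(-1, grid$spacing * 1e3,
                                                     1, 1, 1, 1)),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param path Input path.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  sp <- RNifti::pixdim(img)[seq_len(3)] * 1e-3
  list(volume = vol, grid = image_grid(dim(vol), sp))
}

#' Write / read a multi-angle projection stack
#'
#' Per-angle 2D projections are stored as a single NIfTI whose third axis
#' enumerates angles, with the angle list (degrees) in a YAML sidecar next
#' to the image (`<path>.angles.yaml`). The in-plane spacing goes in the
#' header; the third pixel dimension is a dummy.
#'
#' @param stack Array `nx x nz x n_angles` (projections stacked along the
#'   third axis), or a list of 2D matrices.
#' @param grid The 2D [image_grid()] the projections live on.
#' @param angles Numeric angles in degrees, one per stack slice.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `read_projections`: list with `stack`, `grid`, `angles`.
#' @export
write_projections <- function(stack, grid, angles, path) {
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 3, grid$dims == 2L,
            dim(stack)[3] == length(angles))
  img <- RNifti::asNifti(stack * 1.0,
                         reference = list(pixdim = c(-1, grid$spacing * 1e3,
                                                     1, 1, 1, 1, 1)),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  yaml::write_yaml(list(angles_deg = as.numeric(angles)),
                   paste0(path, ".angles.yaml"))
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  if (!file.exists(path)) stop("projection stack not found: ", path)
  side <- paste0(path, ".angles.yaml")
  if (!file.exists(side)) stop("angle metadata sidecar not found: ", side)
  img <- RNifti::readNifti(path)
  stack <- as.array(img)
  sp <- RNifti::pixdim(img)[seq_len(2)] * 1e-3
  angles <- as.numeric(yaml::read_yaml(side)$angles_deg)
  if (length(angles) != dim(stack)[3]) {
    stop("angle sidecar length does not match the stack depth")
  }
  list(stack = stack, grid = image_grid(dim(stack)[1:2], sp), angles = angles)
}
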