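#' Cell-centered image grid
#'
#' A 2D (x, z) or 3D (x, y, z) voxel mesh, cell-centered and symmetric about
#' the scanner isocenter: voxel centers along an axis with `n` voxels and
#' spacing `h` lie at `h * (seq_len(n) - (n + 1) / 2)`.
#'
#' @param shape Integer vector of voxels per axis, length 2 or 3.
#' @param spacing Voxel spacing (m) per axis; recycled if scalar.
#' @return An object of class `image_grid` with fields `shape`, `spacing`,
#'   `origin` (physical coordinate of the first voxel center) and `dims`.
#' @examples
#' g <- image_grid(c(24, 24, 24), 1.5e-4)
#' range(grid_axis(g, 1))
#' @export
image_grid <- function(shape, spacing) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 1))
  spacing <- rep_len(as.numeric(spacing), length(shape))
  stopifnot(all(spacing > 0))
  origin <- -spacing * (shape - 1) / 2
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 dims = length(shape)),
            class = "image_grid")
}

#' @rdname image_grid
#' @param grid An `image_grid`.
#' @param axis Axis index (1-based).
#' @return `grid_axis`: voxel-center coordinates along one axis.
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + grid$spacing[axis] * (seq_len(grid$shape[axis]) - 1)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %s voxels, spacing %s mm, extent %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(1e3 * x$spacing, 3), collapse = " x "),
              paste(signif(1e3 * x$spacing * x$shape, 3), collapse = " x ")))
  invisible(x)
}

# total volume (or area) of one cell
.cell_measure <- function(grid) prod(grid$spacing)

# In-plane (x, z) grid of a 3D grid, or the grid itself if already 2D.
.inplane_grid <- function(grid) {
  if (grid$dims == 2L) return(grid)
  image_grid(grid$shape[c(1, 3)], grid$spacing[c(1, 3)])
}
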