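# Containers: density volumes, particle stacks, 2D masks.
# A density volume is a cubic 3D array (even side) with a physical pixel
# size in Angstrom per voxel.  The rotation/projection centre is voxel
# N/2 (0-based) in every axis; voxel i holds coordinate i - N/2.

#' Create a density volume
#'
#' @param grid Cubic 3D numeric array with an even side.
#' @param pixel_size Pixel size in Angstrom per voxel.
#' @return Object of class `density_volume`.
#' @export
density_volume <- function(grid, pixel_size = 1) {
  d <- dim(grid)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop_invalid("volume grid must be a cubic 3D array")
  if (d[1] %% 2L != 0L) stop_invalid("volume side must be even")
  if (any(!is.finite(grid))) stop_invalid("volume values must be finite")
  check_finite(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop_invalid("pixel_size must be positive")
  structure(list(grid = grid, pixel_size = pixel_size),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  n <- dim(x$grid)[1]
  cat(sprintf("density_volume: %d^3 voxels, %.3g A/voxel, range [%.4g, %.4g]\n",
              n, x$pixel_size, min(x$grid), max(x$grid)))
  invisible(x)
}

vol_side <- function(vol) dim(vol$grid)[1]

as_volume_grid <- function(vol) {
  if (inherits(vol, "density_volume")) vol$grid else vol
}

# radius (voxels, about the box centre) of the bounding sphere of the
# density above tol * max|grid|; used to restrict projection integrals
support_radius <- function(vol, tol = 1e-5) {
  g <- as_volume_grid(vol)
  n <- dim(g)[1]
  mx <- max(abs(g))
  if (mx == 0) return(0)
  idx <- which(abs(g) > tol * mx, arr.ind = TRUE)
  cc <- sweep(idx - 1, 2, n / 2)
  sqrt(max(rowSums(cc^2)))
}

#' Create a particle stack
#'
#' A set of 2D particle images with an optional per-particle parameter
#' table and optional ground-truth bookkeeping from the synthetic
#' generator.
#'
#' @param images `n x n x m` numeric array of particle images.
#' @param pixel_size Angstrom per pixel.
#' @param params Optional data frame with columns `index`, `phi`, `theta`,
#'   `psi`, `x`, `y` and optionally `defocus_group`, `ccc`.
#' @param truth Optional list of per-particle ground-truth records.
#' @return Object of class `particle_stack`.
#' @export
particle_stack <- function(images, pixel_size = 1, params = NULL,
                           truth = NULL) {
  d <- dim(images)
  if (length(d) == 2L) { images <- array(images, c(d, 1L)); d <- dim(images) }
  if (length(d) != 3L || d[1] != d[2])
    stop_invalid("images must be an n x n x m array")
  if (!is.null(params) && nrow(params) != d[3])
    stop_invalid("parameter table row count must match the stack size")
  structure(list(images = images, pixel_size = pixel_size,
                 params = params, truth = truth),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("particle_stack: %d images of %d x %d px, %.3g A/px%s\n",
              d[3], d[1], d[2], x$pixel_size,
              if (is.null(x$truth)) "" else " (with ground truth)"))
  invisible(x)
}

n_particles <- function(stack) dim(stack$images)[3]

#' Circular 2D mask
#'
#' Binary (or cosine-soft-edged) round mask used to restrict the
#' cross-correlation to the target module footprint.
#'
#' @param n Image side in pixels.
#' @param diameter Mask diameter in pixels.
#' @param center Mask centre offset from the image centre, pixels.
#' @param soft_edge Width of a cosine edge in pixels (0 = hard).
#' @return An `n x n` matrix of weights in `[0, 1]`.
#' @export
circular_mask <- function(n, diameter, center = c(0, 0), soft_edge = 0) {
  check_finite(c(n, diameter, center, soft_edge), "mask spec")
  if (diameter <= 0) stop_invalid("mask diameter must be positive")
  u <- seq_len(n) - 1 - n / 2
  r <- sqrt(outer((u - center[1])^2, (u - center[2])^2, "+"))
  rad <- diameter / 2
  if (soft_edge <= 0) return((r <= rad) * 1)
  w <- matrix(0, n, n)
  w[r <= rad] <- 1
  band <- r > rad & r < rad + soft_edge
  w[band] <- 0.5 * (1 + cos(pi * (r[band] - rad) / soft_edge))
  w
}
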