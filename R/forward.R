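## Ballistic straight-ray forward model: voxel traversal, Mueller-matrix
## chains along each ray, polarization-resolved intensities, shot noise.

## Intensity normalization: raw co-polarized transmission of an empty path
## through a matched generator/analyzer pair is 1/2 of the unpolarized
## source; all intensities are reported relative to that maximum.
copol_norm <- function() 2

#' Projection set container
#'
#' Intensity images for every (projection, polarization set) pair, stored
#' as an array of dimension `(n_k, n_j, 16, n_proj)` together with the
#' acquisition geometry. Use [get_image()] to pull a single image.
#'
#' @param intensities 4D array `(n_k, n_j, 16, n_proj)`.
#' @param geometry The [acq_geometry()] the stack was simulated or
#'   measured with (its `angles` rows index the 4th dimension).
#' @param meta Optional named list carried along (seed, noise settings).
#' @return Object of class `projection_set`.
#' @export
projection_set <- function(intensities, geometry, meta = list()) {
  stopifnot(length(dim(intensities)) == 4, dim(intensities)[3] == 16,
            dim(intensities)[4] == nrow(geometry$angles))
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(intensities = intensities, geometry = geometry,
                 meta = meta),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "Projection set: %d projections x %d polarization sets, %d x %d px\n",
    d[4], d[3], d[1], d[2]))
  invisible(x)
}

#' Extract one intensity image
#'
#' @param ps A [projection_set()].
#' @param projection Projection index (row of `geometry$angles`).
#' @param pol_set Polarization set index 1..16 (see [pol_set_table()]).
#' @return `n_k x n_j` matrix.
#' @export
get_image <- function(ps, projection, pol_set) {
  ps$intensities[, , pol_set, projection]
}

## Internal: radians angle vectors from a geometry.
angles_rad <- function(geometry) {
  list(alpha = geometry$angles$alpha * pi / 180,
       beta = geometry$angles$beta * pi / 180)
}

## Internal: 2*pi*d/lambda, the retardance per unit birefringence.
delta_factor <- function(grid) 2 * pi * grid$d / grid$lambda

#' Ordered voxel path of one detector ray
#'
#' Samples the ray landing on pixel `(k, j)` at a fixed step of one voxel
#' size along the beam, reporting the ordered in-grid voxel indices from
#' source to sensor. Every sample carries the constant path length `d`.
#'
#' @param grid A [voxel_grid()].
#' @param alpha,beta Projection angles, degrees.
#' @param pixel Integer `c(k, j)` pixel index (1-based).
#' @param n_pixels Detector raster; defaults to the grid cross-section.
#' @return List with `voxels` (n x 3 matrix of 1-based indices, ordered
#'   source to sensor) and `lengths` (constant `d` per sample).
#' @export
ray_voxel_path <- function(grid, alpha, beta, pixel, n_pixels = NULL) {
  if (is.null(n_pixels)) n_pixels <- c(grid$dims[1], grid$dims[2])
  stopifnot(pixel[1] >= 1, pixel[1] <= n_pixels[1],
            pixel[2] >= 1, pixel[2] <= n_pixels[2])
  vox <- cpp_ray_path(as.integer(grid$dims), alpha * pi / 180,
                      beta * pi / 180, as.integer(pixel[1]),
                      as.integer(pixel[2]), as.integer(n_pixels[1]),
                      as.integer(n_pixels[2]))
  colnames(vox) <- c("ix", "iy", "iz")
  list(voxels = vox, lengths = rep(grid$d, nrow(vox)))
}

#' Cumulative Mueller-matrix image of one projection
#'
#' Chains the per-voxel retarder matrices along every detector ray
#' (left-multiplicatively: the voxel nearest the sensor is the leftmost
#' factor) and returns the per-pixel sample Mueller matrix.
#'
#' @inheritParams ray_voxel_path
#' @return Array `(4, 4, n_k, n_j)`.
#' @export
project_mueller <- function(grid, alpha, beta, n_pixels = NULL) {
  if (is.null(n_pixels)) n_pixels <- c(grid$dims[1], grid$dims[2])
  cpp_project_mueller(grid$phi, grid$psi, grid$n_e, grid$absorption,
                      as.integer(grid$dims), grid$n_o, delta_factor(grid),
                      alpha * pi / 180, beta * pi / 180,
                      as.integer(n_pixels[1]), as.integer(n_pixels[2]))
}

#' Simulate the polarization-resolved projection stack
#'
#' For every projection angle pair and every one of the 16
#' generator/analyzer polarization sets, computes
#' `I = S^T M_PSA M_chain M_PSG S` per detector pixel, normalised to the
#' co-polarized empty-path maximum.
#'
#' @param grid A [voxel_grid()].
#' @param geometry An [acq_geometry()]; its `d`, `lambda`, `n_o` override
#'   the grid's copies for consistency checks.
#' @return A [projection_set()].
#' @export
simulate_intensities <- function(grid, geometry = acq_geometry()) {
  np <- detector_raster(grid, geometry)
  ang <- angles_rad(geometry)
  mats <- pol_set_matrices()
  ints <- cpp_forward(grid$phi, grid$psi, grid$n_e, grid$absorption,
                      as.integer(grid$dims), grid$n_o, delta_factor(grid),
                      ang$alpha, ang$beta, as.integer(np[1]),
                      as.integer(np[2]), mats$generator, mats$analyzer, copol_norm())
  projection_set(ints, geometry, meta = list(noise = FALSE))
}

#' Apply 12-bit camera shot noise
#'
#' Scales the stack so that its global maximum maps to the camera full
#' well, replaces every pixel by a Poisson draw, and rescales back. The
#' global RNG state is left untouched when a `seed` is given.
#'
#' @param ps A [projection_set()].
#' @param full_well Counts at the global intensity maximum (default 4095,
#'   a 12-bit sensor).
#' @param seed Integer seed for reproducible noise, or `NULL` to use the
#'   current RNG stream.
#' @return A [projection_set()] with Poisson-noisy intensities.
#' @export
add_shot_noise <- function(ps, full_well = 4095, seed = NULL) {
  x <- ps$intensities
  if (any(x < 0)) stop("negative intensities")
  peak <- max(x)
  if (peak == 0) return(ps)
  counts <- x / peak * full_well
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  noisy <- array(stats::rpois(length(counts), counts), dim(counts))
  out <- ps
  out$intensities <- noisy / full_well * peak
  out$meta$noise <- TRUE
  out$meta$full_well <- full_well
  out$meta$noise_seed <- seed
  out
}
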