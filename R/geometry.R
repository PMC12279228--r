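## Acquisition geometry, voxel grid container, and the counting/resolution
## arithmetic of a dual-axis polarimetric tomography scan.

#' Default dual-axis tomographic angle set
#'
#' Rotation angles in 14-degree steps over a full turn (26 values) at tilt
#' angles 0 and +/- 6.8 degrees, i.e. 78 projections, matching a dual-axis
#' goniometer scan. Out-of-plane c-axis components are only identifiable
#' with at least two tilt axes.
#'
#' @param rot_step Rotation increment, degrees.
#' @param tilts Tilt angles, degrees.
#' @return data.frame with columns `alpha`, `beta` in degrees.
#' @export
default_scan_angles <- function(rot_step = 14, tilts = c(0, -6.8, 6.8)) {
  ## full turn: 0, rot_step, ... excluding the 360-degree alias of 0,
  ## e.g. 14-degree steps give 26 angles 0..350
  alphas <- rot_step * seq(0, ceiling(360 / rot_step) - 1)
  data.frame(alpha = rep(alphas, times = length(tilts)),
             beta = rep(tilts, each = length(alphas)))
}

#' Acquisition geometry
#'
#' Bundles everything the forward model needs besides the voxel grid: the
#' projection angle list, wavelength, voxel size, ordinary index of the
#' index-matching liquid, and the detector raster.
#'
#' @param angles data.frame with columns `alpha`, `beta` in degrees (stored
#'   in degrees, converted to radians internally).
#' @param d Voxel size = detector pixel size, micrometres.
#' @param lambda Wavelength, micrometres (default 0.625, a 625 nm red LED).
#' @param n_o Ordinary index, fixed to the immersion-liquid value.
#' @param n_pixels Detector raster `c(n_k, n_j)`; defaults to the grid
#'   cross-section when the forward model is invoked.
#' @param full_well Camera full-well used by the shot-noise model (12-bit).
#' @return Object of class `acq_geometry`.
#' @export
acq_geometry <- function(angles = default_scan_angles(), d = 23.44,
                         lambda = 0.625, n_o = 1.48, n_pixels = NULL,
                         full_well = 4095) {
  stopifnot(is.data.frame(angles), all(c("alpha", "beta") %in% names(angles)),
            d > 0, lambda > 0, n_o > 0)
  structure(list(angles = angles, d = d, lambda = lambda, n_o = n_o,
                 n_pixels = n_pixels, full_well = full_well),
            class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat("Acquisition geometry:\n")
  cat(sprintf("  %d projections (%d rotation x %d tilt angles)\n",
              nrow(x$angles), length(unique(x$angles$alpha)),
              length(unique(x$angles$beta))))
  cat(sprintf("  voxel size %.4g um, wavelength %.4g um, n_o %.4g\n",
              x$d, x$lambda, x$n_o))
  invisible(x)
}

#' Voxel grid of per-voxel index-ellipsoid parameters
#'
#' Holds the four per-voxel optical parameter arrays in the object frame:
#' c-axis polar angle `phi` in `[0, pi]`, azimuth `psi` in `[0, 2 pi)`,
#' extraordinary index `n_e`, and absorption `A` (attenuation per voxel
#' path length, so one voxel transmits `exp(-A)`). The ordinary index `n_o`
#' is a single global constant, not a per-voxel unknown.
#'
#' @param phi,psi,n_e,absorption Numeric 3D arrays of identical dimension
#'   `(nx, ny, nz)`.
#' @param n_o Ordinary refractive index.
#' @param d Voxel size, micrometres.
#' @param lambda Wavelength, micrometres.
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(phi, psi, n_e, absorption = NULL, n_o = 1.48,
                       d = 23.44, lambda = 0.625) {
  dims <- dim(phi)
  stopifnot(length(dims) == 3, identical(dim(psi), dims),
            identical(dim(n_e), dims))
  if (is.null(absorption)) absorption <- array(0, dims)
  stopifnot(identical(dim(absorption), dims), all(absorption >= 0))
  if (any(abs(n_e - n_o) > 0.01 + 1e-12)) {
    stop("|n_e - n_o| exceeds 0.01: outside the small-birefringence ",
         "regime assumed by the ballistic forward model")
  }
  structure(list(phi = phi, psi = psi, n_e = n_e, absorption = absorption,
                 n_o = n_o, d = d, lambda = lambda, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid %d x %d x %d, d = %.4g um, n_o = %.4g\n",
              x$dims[1], x$dims[2], x$dims[3], x$d, x$n_o))
  cat(sprintf("  birefringence n_e - n_o in [%.2e, %.2e]\n",
              min(x$n_e - x$n_o), max(x$n_e - x$n_o)))
  invisible(x)
}

## Detector raster for a grid: transverse axis k covers nx, vertical axis j
## (the rotation axis) covers ny.
detector_raster <- function(grid, geometry = NULL) {
  if (!is.null(geometry) && !is.null(geometry$n_pixels)) {
    return(geometry$n_pixels)
  }
  c(grid$dims[1], grid$dims[2])
}

#' Datapoint and parameter accounting of a scan
#'
#' For a grid of `shape` voxels scanned at `n_rotations x n_tilts`
#' projections with `n_pol_sets` polarization sets, counts measured
#' datapoints (projections x polarization sets x projected pixel raster,
#' the raster being the `nx x ny` grid cross-section) against the unknowns
#' (3 per voxel, or 4 when the absorption is included).
#'
#' @param shape Integer grid dimensions `c(nx, ny, nz)`.
#' @param n_rotations,n_tilts,n_pol_sets Positive integers.
#' @return List with `n_projections`, `n_images`, `datapoints`,
#'   `parameters`, `parameters_with_absorption`.
#' @export
count_datapoints <- function(shape, n_rotations = 26, n_tilts = 3,
                             n_pol_sets = 16) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            n_rotations >= 1, n_tilts >= 1, n_pol_sets >= 1)
  n_proj <- n_rotations * n_tilts
  n_vox <- prod(shape)
  list(n_projections = n_proj,
       n_images = n_proj * n_pol_sets,
       datapoints = n_proj * n_pol_sets * shape[1] * shape[2],
       parameters = n_vox * 3,
       parameters_with_absorption = n_vox * 4)
}

#' Object-plane resolution and voxel size from the camera geometry
#'
#' The object-plane sampling is the camera pixel pitch divided by the
#' objective magnification; binning the images by an integer factor to gain
#' depth of field sets the reconstruction voxel size.
#'
#' @param pixel_pitch Camera pixel pitch, micrometres (default 5.86).
#' @param magnification Objective magnification (default 2).
#' @param binning Downsampling factor (default 8).
#' @return List with `resolution` and `voxel_size` in micrometres.
#' @export
camera_voxel_size <- function(pixel_pitch = 5.86, magnification = 2,
                              binning = 8) {
  stopifnot(pixel_pitch > 0, magnification > 0, binning >= 1)
  res <- pixel_pitch / magnification
  list(resolution = res, voxel_size = res * binning)
}
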