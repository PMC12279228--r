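## Synthetic ground-truth volumes: the helical validation phantom and
## uniform-random initial grids, plus a one-call noisy dataset builder.

#' Helical (spiral) validation phantom
#'
#' A tube of birefringent material wound as a single helical pitch inside
#' the grid, with the c-axis everywhere tangent to the helix centerline.
#' Voxels whose center lies within `radius` (Euclidean) of the continuous
#' centerline are foreground; the birefringence and the absorption both
#' ramp linearly along the helix arc over their configured ranges (a
#' gradual spatial variation). Background voxels have `n_e = n_o` and zero
#' absorption.
#'
#' The helix axis runs along the second (longest) grid dimension, centred;
#' the helix radius is chosen so the tube just fits inside the transverse
#' cross-section.
#'
#' @param shape Grid dimensions, default `c(15, 25, 15)` voxels.
#' @param pitch Length of the single helical turn along the axis, voxels
#'   (default 22).
#' @param radius Tube cross-section radius, voxels (default 3).
#' @param handedness `"right"` or `"left"`.
#' @param dn_range Birefringence `n_e - n_o` range, default
#'   `c(0.001, 0.002)`.
#' @param absorption_range Per-voxel absorption range, default
#'   `c(0.1, 0.3)`.
#' @param helix_radius Centerline radius in voxels; default fits the tube
#'   into the transverse section with a half-voxel margin.
#' @param n_o,d,lambda Optical constants of the grid.
#' @param n_centerline Dense centerline samples used for the
#'   distance-to-centerline test.
#' @return A [voxel_grid()] with attribute `foreground` (logical array).
#' @export
make_spiral <- function(shape = c(15, 25, 15), pitch = 22, radius = 3,
                        handedness = c("right", "left"),
                        dn_range = c(0.001, 0.002),
                        absorption_range = c(0.1, 0.3),
                        helix_radius = NULL, n_o = 1.48, d = 23.44,
                        lambda = 0.625, n_centerline = 4000) {
  handedness <- match.arg(handedness)
  stopifnot(length(shape) == 3, pitch >= 1, radius >= 0,
            all(dn_range >= 0), diff(dn_range) >= 0)
  if (pitch > shape[2]) stop("helical pitch exceeds the grid axis")
  if (is.null(helix_radius)) {
    helix_radius <- (min(shape[1], shape[3]) - 1) / 2 - radius - 0.5
  }
  if (helix_radius < 0 ||
      helix_radius + radius > (min(shape[1], shape[3]) - 1) / 2 + 0.5) {
    stop("tube does not fit inside the grid cross-section")
  }
  hand <- if (handedness == "right") 1 else -1

  cx <- (shape[1] - 1) / 2
  cy <- (shape[2] - 1) / 2
  cz <- (shape[3] - 1) / 2
  y0 <- cy - pitch / 2

  ## dense centerline: s in [0, 1] covers one full turn along the axis
  s <- seq(0, 1, length.out = n_centerline)
  gam <- hand * 2 * pi * s
  px <- cx + helix_radius * cos(gam)
  py <- y0 + pitch * s
  pz <- cz + helix_radius * sin(gam)
  ## unit tangent d(center)/ds
  tx <- -helix_radius * hand * 2 * pi * sin(gam)
  ty <- rep(pitch, n_centerline)
  tz <- helix_radius * hand * 2 * pi * cos(gam)
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  tx <- tx / tn; ty <- ty / tn; tz <- tz / tn

  phi <- array(0, shape)
  psi <- array(0, shape)
  n_e <- array(n_o, shape)
  ab <- array(0, shape)
  fg <- array(FALSE, shape)
  for (iz in seq_len(shape[3])) for (iy in seq_len(shape[2])) {
    ## squared distance in (y, z) first to prune the x loop cheaply
    dy2 <- (py - (iy - 1))^2
    dz2 <- (pz - (iz - 1))^2
    for (ix in seq_len(shape[1])) {
      d2 <- (px - (ix - 1))^2 + dy2 + dz2
      m <- which.min(d2)
      if (d2[m] <= radius^2) {
        fg[ix, iy, iz] <- TRUE
        ## c-axis angles from the tangent: phi polar from +z (object frame
        ## third axis), psi azimuth in (x, y)
        phi[ix, iy, iz] <- acos(max(-1, min(1, tz[m])))
        psi[ix, iy, iz] <- atan2(ty[m], tx[m]) %% (2 * pi)
        n_e[ix, iy, iz] <- n_o + dn_range[1] + diff(dn_range) * s[m]
        ab[ix, iy, iz] <- absorption_range[1] +
          diff(absorption_range) * s[m]
      }
    }
  }
  g <- voxel_grid(phi, psi, n_e, ab, n_o = n_o, d = d, lambda = lambda)
  attr(g, "foreground") <- fg
  attr(g, "centerline") <- list(s = s, x = px, y = py, z = pz,
                                tangent = cbind(tx, ty, tz))
  g
}

#' Uniform-random voxel grid
#'
#' Independent uniform draws per voxel: `phi` in `[0, pi]`, `psi` in
#' `[0, 2 pi)`, and `n_e` in `n_o + dn_range`. Used as the randomized
#' initialization of the reconstruction. Deterministic per seed; the
#' global RNG state is restored afterwards.
#'
#' @param shape Grid dimensions.
#' @param dn_range Birefringence range of the draw.
#' @param n_o,d,lambda Optical constants.
#' @param seed Integer seed.
#' @return A [voxel_grid()].
#' @export
make_random_init <- function(shape, dn_range = c(0, 0.002), n_o = 1.48,
                             d = 23.44, lambda = 0.625, seed = 1) {
  stopifnot(length(shape) == 3, diff(range(dn_range)) >= 0)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  n <- prod(shape)
  voxel_grid(array(stats::runif(n, 0, pi), shape),
             array(stats::runif(n, 0, 2 * pi), shape),
             array(n_o + stats::runif(n, min(dn_range), max(dn_range)),
                   shape),
             n_o = n_o, d = d, lambda = lambda)
}

#' Simulate a complete synthetic dataset
#'
#' Forward-projects a ground-truth grid at the given geometry and
#' optionally applies 12-bit shot noise, bundling the truth for recovery
#' experiments.
#'
#' @param grid Ground-truth [voxel_grid()].
#' @param geometry An [acq_geometry()].
#' @param noise Apply Poisson shot noise?
#' @param seed Noise seed.
#' @return List with `projections` (a [projection_set()]) and `truth`.
#' @export
make_dataset <- function(grid, geometry = acq_geometry(), noise = TRUE,
                         seed = 1) {
  ps <- simulate_intensities(grid, geometry)
  if (noise) ps <- add_shot_noise(ps, geometry$full_well, seed = seed)
  list(projections = ps, truth = grid)
}
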