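## On-disk container: a self-describing directory with a YAML metadata
## file and CSV payloads. Angles are stored in degrees, all internal math
## is in radians. Optional per-image TIFF export for visual inspection.

#' Write a projection set to disk
#'
#' Creates (or overwrites) a directory holding `meta.yaml` (geometry,
#' wavelength, voxel size, ordinary index, full well, any simulation
#' metadata such as the noise seed), `angles.csv` and `intensities.csv`
#' (one row per (projection, polarization set), pixel columns in
#' column-major order).
#'
#' @param ps A [projection_set()].
#' @param dir Output directory path.
#' @return `dir`, invisibly.
#' @export
write_projections <- function(ps, dir) {
  parent <- dirname(dir)
  if (!dir.exists(parent)) stop("parent directory does not exist: ", parent)
  dir.create(dir, showWarnings = FALSE)
  d <- dim(ps$intensities)
  g <- ps$geometry
  meta <- list(format = "muellertomo-projections", version = 1L,
               n_k = d[1], n_j = d[2], n_pol_sets = d[3],
               n_projections = d[4], d_um = g$d, lambda_um = g$lambda,
               n_o = g$n_o, full_well = g$full_well,
               meta = ps$meta)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  data.table::fwrite(g$angles, file.path(dir, "angles.csv"))
  ## rows = (pol set, projection) with pol set fastest; columns = pixels
  ## in column-major (k fastest) order
  flat <- t(matrix(ps$intensities, nrow = d[1] * d[2]))
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(dir, "intensities.csv"))
  invisible(dir)
}

#' Read a projection set written by [write_projections()]
#'
#' @param dir Directory path.
#' @return A [projection_set()].
#' @export
read_projections <- function(dir) {
  mp <- file.path(dir, "meta.yaml")
  if (!file.exists(mp)) stop("not a projection container: ", dir)
  meta <- yaml::read_yaml(mp)
  if (!identical(meta$format, "muellertomo-projections")) {
    stop("unrecognized container format in ", dir)
  }
  angles <- as.data.frame(data.table::fread(file.path(dir, "angles.csv")))
  flat <- as.matrix(data.table::fread(file.path(dir, "intensities.csv")))
  ints <- array(t(flat), c(meta$n_k, meta$n_j, meta$n_pol_sets,
                           meta$n_projections))
  geom <- acq_geometry(angles, d = meta$d_um, lambda = meta$lambda_um,
                       n_o = meta$n_o, n_pixels = c(meta$n_k, meta$n_j),
                       full_well = meta$full_well)
  projection_set(ints, geom, meta = meta$meta)
}

#' Write a reconstructed (or ground-truth) tomogram
#'
#' Directory with `meta.yaml` and `volume.csv` (columns `ix, iy, iz, phi,
#' psi, n_e, absorption`); optionally the optimization traces as
#' `trace.csv`.
#'
#' @param grid A [voxel_grid()].
#' @param dir Output directory.
#' @param trace Optional data.frame/list of per-iteration traces.
#' @param extra Named list merged into the metadata (e.g. config, seed).
#' @return `dir`, invisibly.
#' @export
write_tomogram <- function(grid, dir, trace = NULL, extra = list()) {
  parent <- dirname(dir)
  if (!dir.exists(parent)) stop("parent directory does not exist: ", parent)
  dir.create(dir, showWarnings = FALSE)
  meta <- c(list(format = "muellertomo-tomogram", version = 1L,
                 dims = as.integer(grid$dims), d_um = grid$d,
                 lambda_um = grid$lambda, n_o = grid$n_o), extra)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  idx <- arrayInd(seq_len(prod(grid$dims)), grid$dims)
  df <- data.frame(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
                   phi = as.vector(grid$phi), psi = as.vector(grid$psi),
                   n_e = as.vector(grid$n_e),
                   absorption = as.vector(grid$absorption))
  data.table::fwrite(df, file.path(dir, "volume.csv"))
  if (!is.null(trace)) {
    tr <- trace[vapply(trace, length, 1L) > 0]
    data.table::fwrite(as.data.frame(tr), file.path(dir, "trace.csv"))
  }
  invisible(dir)
}

#' Read a tomogram written by [write_tomogram()]
#'
#' @param dir Directory path.
#' @return List with `grid` (a [voxel_grid()]), `trace` (data.frame or
#'   `NULL`) and `meta`.
#' @export
read_tomogram <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  if (!identical(meta$format, "muellertomo-tomogram")) {
    stop("unrecognized container format in ", dir)
  }
  dims <- as.integer(unlist(meta$dims))
  df <- data.table::fread(file.path(dir, "volume.csv"))
  grid <- voxel_grid(array(df$phi, dims), array(df$psi, dims),
                     array(df$n_e, dims), array(df$absorption, dims),
                     n_o = meta$n_o, d = meta$d_um,
                     lambda = meta$lambda_um)
  tp <- file.path(dir, "trace.csv")
  trace <- if (file.exists(tp)) as.data.frame(data.table::fread(tp))
  list(grid = grid, trace = trace, meta = meta)
}

#' Export projection images as TIFF files
#'
#' One 32-bit float TIFF per (projection, polarization set) pair, for
#' inspection in standard image viewers. Requires the `tiff` package.
#'
#' @param ps A [projection_set()].
#' @param dir Output directory.
#' @param projections,pol_sets Indices to export (defaults: all).
#' @return Paths written, invisibly.
#' @export
export_tiff <- function(ps, dir, projections = NULL, pol_sets = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("TIFF export requires the 'tiff' package")
  }
  d <- dim(ps$intensities)
  if (is.null(projections)) projections <- seq_len(d[4])
  if (is.null(pol_sets)) pol_sets <- seq_len(d[3])
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in projections) for (l in pol_sets) {
    p <- file.path(dir, sprintf("proj%03d_set%02d.tiff", i, l))
    tiff::writeTIFF(t(get_image(ps, i, l)) / max(ps$intensities, 1), p,
                    bits.per.sample = 32L)
    paths <- c(paths, p)
  }
  invisible(paths)
}
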