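## Conventional Mueller-polarimetry data reduction: recover the per-pixel
## sample Mueller matrix from the 16 polarization-resolved intensities and
## extract cumulative retardance / fast-axis / transmission maps.

## Generator and analyzer state matrices of the four-state scheme:
## A rows are S^T M_PSA per analyzer state, G columns are M_PSG S per
## generator state. Both are invertible for the RCP/LCP/LP0/LP45 set.
state_matrices <- function() {
  states <- polarization_states()
  A <- 0.5 * cbind(1, do.call(rbind, states))
  G <- t(A)
  if (abs(det(A)) < 1e-12) {
    stop("polarization state matrix is singular")  # cannot happen here
  }
  list(A = A, G = G)
}

#' Synthesize the per-pixel Mueller matrix from 16 intensities
#'
#' Inverts the bilinear measurement model `I[a, g] = (S^T M_PSA^a) M
#' (M_PSG^g S)`: with the analyzer rows stacked into a matrix `A` and the
#' generator columns into `G`, the sample matrix is `M = A^-1 I16 G^-1`.
#' The stack's co-polarized normalization is undone first, so an empty
#' path yields exactly the identity matrix and the roundtrip with
#' [simulate_intensities()] is exact for noiseless input.
#'
#' @param ps A [projection_set()].
#' @param projection Projection index.
#' @return Array `(4, 4, n_k, n_j)` of Mueller matrices.
#' @export
synthesize_mueller <- function(ps, projection = 1) {
  sm <- state_matrices()
  Ainv <- solve(sm$A)
  Ginv <- solve(sm$G)
  d <- dim(ps$intensities)
  tab <- pol_set_table()
  a_idx <- match(tab$analyzer, names(polarization_states()))
  g_idx <- match(tab$generator, names(polarization_states()))
  out <- array(0, c(4, 4, d[1], d[2]))
  raw <- ps$intensities[, , , projection] / copol_norm()
  i16 <- matrix(0, 4, 4)
  for (ik in seq_len(d[1])) for (ij in seq_len(d[2])) {
    i16[cbind(a_idx, g_idx)] <- raw[ik, ij, ]
    out[, , ik, ij] <- Ainv %*% i16 %*% Ginv
  }
  out
}

#' Extract linear-retarder parameters from a Mueller matrix
#'
#' Interprets `M` as (the nearest) scalar-transmission linear retarder:
#' transmission from element `[1,1]`, retardance on the principal branch
#' `[0, pi]` from the circular block (`cos delta` from `[4,4]`, `sin
#' delta` from the `[2,4]`/`[3,4]` pair), and the fast-axis angle from a
#' two-argument arctangent over the `2 theta`-bearing elements, folded
#' into `[0, pi)`. For a cumulative matrix of many differently oriented
#' retarders the form is not exact; pixels whose normalized 3x3 block
#' departs from orthogonality by more than `tol` are flagged rather than
#' silently decomposed.
#'
#' @param M 4x4 Mueller matrix, or array `(4, 4, ...)` of them.
#' @param tol Orthogonality / clipping tolerance.
#' @return For a single matrix, list `(delta, theta, transmission,
#'   flagged)`; for an array, a list of arrays of the same trailing shape.
#' @export
extract_retarder <- function(M, tol = 1e-6) {
  if (is.matrix(M)) return(extract_retarder_one(M, tol))
  d <- dim(M)
  sh <- d[-(1:2)]
  n <- prod(sh)
  Mm <- matrix(M, 16, n)
  delta <- theta <- trans <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    r <- extract_retarder_one(matrix(Mm[, i], 4, 4), tol)
    delta[i] <- r$delta; theta[i] <- r$theta
    trans[i] <- r$transmission; flagged[i] <- r$flagged
  }
  list(delta = array(delta, sh), theta = array(theta, sh),
       transmission = array(trans, sh), flagged = array(flagged, sh))
}

extract_retarder_one <- function(M, tol = 1e-6) {
  t_lr <- M[1, 1]
  if (t_lr <= 0) {
    return(list(delta = 0, theta = 0, transmission = t_lr, flagged = TRUE))
  }
  B <- M[2:4, 2:4] / t_lr
  flagged <- max(abs(crossprod(B) - diag(3))) > max(tol, 1e-6) ||
    max(abs(M[1, 2:4])) > max(tol, 1e-6) * t_lr ||
    max(abs(M[2:4, 1])) > max(tol, 1e-6) * t_lr
  cd <- M[4, 4] / t_lr
  if (abs(cd) > 1 + tol) flagged <- TRUE
  cd <- max(-1, min(1, cd))
  ## sin(delta) >= 0 on the principal branch; its magnitude lives in the
  ## [2,4]/[3,4] column: M[2,4] = -t sd sin2theta, M[3,4] = t sd cos2theta
  sd <- sqrt(M[2, 4]^2 + M[3, 4]^2) / t_lr
  delta <- atan2(sd, cd)
  if (sd > 1e-9) {
    theta <- 0.5 * atan2(-M[2, 4], M[3, 4])
  } else if (1 - cd > 1e-9) {
    ## half-wave-like case: recover 4 theta from the linear block
    theta <- 0.25 * atan2(2 * M[2, 3], M[2, 2] - M[3, 3])
  } else {
    theta <- 0  # identity: fast axis undefined, return 0 by convention
  }
  list(delta = delta, theta = theta %% pi, transmission = t_lr,
       flagged = flagged)
}

#' Cumulative retardance / fast-axis map of one projection
#'
#' Synthesizes the per-pixel Mueller matrices of a projection and extracts
#' the total linear retardance, fast-axis angle and isotropic transmission
#' integrated through the sample thickness.
#'
#' @param ps A [projection_set()].
#' @param projection Projection index.
#' @return Object of class `retardance_map`: list of `n_k x n_j` arrays
#'   `delta`, `theta`, `transmission`, `flagged`, plus the projection
#'   angles.
#' @export
retardance_map <- function(ps, projection = 1) {
  M <- synthesize_mueller(ps, projection)
  r <- extract_retarder(M)
  structure(list(delta = r$delta, theta = r$theta,
                 transmission = r$transmission, flagged = r$flagged,
                 alpha = ps$geometry$angles$alpha[projection],
                 beta = ps$geometry$angles$beta[projection]),
            class = "retardance_map")
}

#' @export
print.retardance_map <- function(x, ...) {
  cat(sprintf(
    "Retardance map at alpha = %g, beta = %g deg: delta in [%.3g, %.3g] rad\n",
    x$alpha, x$beta, min(x$delta), max(x$delta)))
  invisible(x)
}

#' Export a fast-axis tick map
#'
#' Writes one tick per (optionally downsampled) pixel to CSV (columns
#' `k`, `j`, `theta`, `delta`, `transmission`), the standard way of
#' displaying fast-axis fields: tick direction is the fast-axis angle,
#' tick length/color carries the retardance. Optionally renders the ticks
#' to a PDF.
#'
#' @param map A [retardance_map()].
#' @param path CSV output path.
#' @param downsample Keep every `downsample`-th pixel along both axes.
#' @param pdf_path Optional PDF render path.
#' @return The exported data.frame, invisibly.
#' @export
tickmap_export <- function(map, path, downsample = 1, pdf_path = NULL) {
  d <- dim(map$delta)
  ks <- seq(1, d[1], by = downsample)
  js <- seq(1, d[2], by = downsample)
  df <- expand.grid(k = ks, j = js)
  df$theta <- map$theta[cbind(df$k, df$j)]
  df$delta <- map$delta[cbind(df$k, df$j)]
  df$transmission <- map$transmission[cbind(df$k, df$j)]
  data.table::fwrite(df, path)
  if (!is.null(pdf_path)) {
    grDevices::pdf(pdf_path, width = 6, height = 6 * d[2] / d[1])
    on.exit(grDevices::dev.off())
    len <- 0.45 * downsample * df$delta / max(max(df$delta), 1e-12)
    graphics::plot(NA, xlim = c(0, d[1] + 1), ylim = c(0, d[2] + 1),
                   xlab = "k", ylab = "j", asp = 1,
                   main = sprintf("alpha = %g, beta = %g deg",
                                  map$alpha, map$beta))
    graphics::segments(df$k - len * cos(df$theta),
                       df$j - len * sin(df$theta),
                       df$k + len * cos(df$theta),
                       df$j + len * sin(df$theta))
  }
  invisible(df)
}
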