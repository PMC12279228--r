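## Inverse problem: regularized Nesterov-accelerated gradient descent over
## the per-voxel index-ellipsoid parameters (phi, psi, n_e), plus linear
## absorption tomography and ground-truth proximity metrics.

#' Sum-of-squares intensity loss
#'
#' `sum((simulated - measured)^2)` over all projections, polarization sets
#' and pixels.
#'
#' @param measured,simulated [projection_set()] objects or arrays of equal
#'   dimension.
#' @return Non-negative scalar, zero iff pixel-wise equality.
#' @export
intensity_loss <- function(measured, simulated) {
  a <- if (inherits(measured, "projection_set")) measured$intensities
       else measured
  b <- if (inherits(simulated, "projection_set")) simulated$intensities
       else simulated
  if (!identical(dim(a), dim(b))) stop("projection sets differ in shape")
  sum((b - a)^2)
}

#' Analytic gradient of the intensity loss
#'
#' Differentiates the full forward model (ray chains of retarder matrices
#' between generator and analyzer) with respect to every voxel's
#' `(phi, psi, n_e)`. For voxel p on a ray the derivative of the chain
#' keeps the products of the matrices after and before p fixed and
#' differentiates the voxel's own matrix through its retardance and
#' fast-axis angle; all other terms vanish. Computed in compiled code with
#' cached per-ray prefix/suffix products.
#'
#' @param grid Current [voxel_grid()] estimate.
#' @param measured A [projection_set()].
#' @param geometry The [acq_geometry()] of the measurement.
#' @param projections Optional integer subset of projection indices
#'   (mini-batch); default all.
#' @return List with `eps_i` (the loss restricted to `projections`) and
#'   gradient arrays `phi`, `psi`, `n_e`.
#' @export
analytic_gradient <- function(grid, measured, geometry = measured$geometry,
                              projections = NULL) {
  np <- detector_raster(grid, geometry)
  d <- dim(measured$intensities)
  if (d[1] != np[1] || d[2] != np[2] ||
      d[4] != nrow(geometry$angles)) {
    stop("measured stack does not match grid/geometry raster")
  }
  if (is.null(projections)) projections <- seq_len(d[4])
  ang <- angles_rad(geometry)
  mats <- pol_set_matrices()
  cpp_gradient(grid$phi, grid$psi, grid$n_e, grid$absorption,
               as.integer(grid$dims), grid$n_o, delta_factor(grid),
               ang$alpha, ang$beta, as.integer(np[1]), as.integer(np[2]),
               mats$generator, mats$analyzer, copol_norm(),
               measured$intensities, as.integer(projections - 1))
}

## 6-neighbour pair sweep: applies f(idx_v, idx_w) for the +1 shift along
## each grid axis, where idx are index triplets expressed as logical array
## slices. Used by both regularizers.
axis_pairs <- function(dims) {
  lapply(1:3, function(ax) {
    n <- dims[ax]
    if (n < 2) return(NULL)
    iv <- lapply(dims, seq_len)
    iw <- lapply(dims, seq_len)
    iv[[ax]] <- 1:(n - 1)
    iw[[ax]] <- 2:n
    list(v = iv, w = iw)
  })
}

#' Orientation smoothing regularizer
#'
#' Penalizes misalignment of the c-axis director between 6-connected
#' neighbour voxels: `sum over pairs of (1 - (c_v . c_w)^2)`. The square
#' makes the penalty invariant under flipping any voxel's c to -c
#' (director symmetry), and it vanishes iff all neighbours are parallel or
#' antiparallel.
#'
#' @param phi,psi Orientation-angle arrays of the grid.
#' @return List with `value` and gradient arrays `grad_phi`, `grad_psi`.
#' @export
smooth_reg_orientation <- function(phi, psi) {
  dims <- dim(phi)
  sp <- sin(phi); cp <- cos(phi); sps <- sin(psi); cps <- cos(psi)
  cx <- sp * cps; cy <- sp * sps; cz <- cp
  dxp <- cp * cps; dyp <- cp * sps; dzp <- -sp     # d c / d phi
  dxs <- -sp * sps; dys <- sp * cps                # d c / d psi (z comp 0)
  val <- 0
  gphi <- array(0, dims); gpsi <- array(0, dims)
  for (pr in axis_pairs(dims)) {
    if (is.null(pr)) next
    v <- pr$v; w <- pr$w
    dot <- do.call(`[`, c(list(cx), v)) * do.call(`[`, c(list(cx), w)) +
           do.call(`[`, c(list(cy), v)) * do.call(`[`, c(list(cy), w)) +
           do.call(`[`, c(list(cz), v)) * do.call(`[`, c(list(cz), w))
    val <- val + sum(1 - dot^2)
    ## d/du_v (1 - dot^2) = -2 dot (dc_v/du . c_w), symmetrically for w
    gv_phi <- -2 * dot *
      (do.call(`[`, c(list(dxp), v)) * do.call(`[`, c(list(cx), w)) +
       do.call(`[`, c(list(dyp), v)) * do.call(`[`, c(list(cy), w)) +
       do.call(`[`, c(list(dzp), v)) * do.call(`[`, c(list(cz), w)))
    gw_phi <- -2 * dot *
      (do.call(`[`, c(list(cx), v)) * do.call(`[`, c(list(dxp), w)) +
       do.call(`[`, c(list(cy), v)) * do.call(`[`, c(list(dyp), w)) +
       do.call(`[`, c(list(cz), v)) * do.call(`[`, c(list(dzp), w)))
    gv_psi <- -2 * dot *
      (do.call(`[`, c(list(dxs), v)) * do.call(`[`, c(list(cx), w)) +
       do.call(`[`, c(list(dys), v)) * do.call(`[`, c(list(cy), w)))
    gw_psi <- -2 * dot *
      (do.call(`[`, c(list(cx), v)) * do.call(`[`, c(list(dxs), w)) +
       do.call(`[`, c(list(cy), v)) * do.call(`[`, c(list(dys), w)))
    gphi <- add_slice(gphi, v, gv_phi)
    gphi <- add_slice(gphi, w, gw_phi)
    gpsi <- add_slice(gpsi, v, gv_psi)
    gpsi <- add_slice(gpsi, w, gw_psi)
  }
  list(value = val, grad_phi = gphi, grad_psi = gpsi)
}

add_slice <- function(arr, idx, delta) {
  cur <- do.call(`[`, c(list(arr), idx))
  do.call(`[<-`, c(list(arr), idx, list(cur + delta)))
}

#' Index smoothing regularizer
#'
#' Quadratic penalty on 6-connected neighbour differences of the
#' extraordinary index: `sum over pairs of (n_v - n_w)^2`; zero iff `n_e`
#' is constant.
#'
#' @param n_e Extraordinary-index array.
#' @return List with `value` and `grad` array.
#' @export
smooth_reg_index <- function(n_e) {
  dims <- dim(n_e)
  val <- 0
  g <- array(0, dims)
  for (pr in axis_pairs(dims)) {
    if (is.null(pr)) next
    dvw <- do.call(`[`, c(list(n_e), pr$v)) -
           do.call(`[`, c(list(n_e), pr$w))
    val <- val + sum(dvw^2)
    g <- add_slice(g, pr$v, 2 * dvw)
    g <- add_slice(g, pr$w, -2 * dvw)
  }
  list(value = val, grad = g)
}

#' One Nesterov-accelerated update
#'
#' Look-ahead form: the gradient is evaluated at `x + momentum * v`, then
#' `v <- momentum * v - lr * g` and `x <- x + v`. With `momentum = 0` this
#' is plain gradient descent.
#'
#' @param x Current parameters (numeric vector/array).
#' @param v Momentum buffer of the same shape.
#' @param gradient Function of one argument returning the gradient at the
#'   look-ahead point.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @return List with updated `x` and `v`.
#' @export
nesterov_step <- function(x, v, gradient, lr, momentum = 0.9) {
  g <- gradient(x + momentum * v)
  if (any(!is.finite(g))) stop("non-finite gradient in Nesterov step")
  v <- momentum * v - lr * g
  list(x = x + v, v = v)
}

#' Reconstruction configuration
#'
#' @param n_iter Iteration budget (one gradient evaluation each).
#' @param lr_orientation,lr_index Learning rates of the angle pair
#'   (phi, psi) and of `n_e`. `n_e` enters the retardance through the
#'   factor `2 pi d / lambda` (~2e2 at 23 um voxels and 625 nm), hence its
#'   much smaller rate.
#' @param momentum Nesterov momentum coefficient.
#' @param block_orientation,block_index Stage-wise alternation: number of
#'   consecutive iterations spent on the orientation angles, then on the
#'   index, repeating.
#' @param w_orientation,w_index Regularizer weights (applied to the raw
#'   neighbour-pair sums).
#' @param batch_size Projections per gradient step; `NULL` uses all
#'   projections (deterministic full-batch descent).
#' @param patience Window length of the divergence guard: when the loss
#'   exceeds its value `patience` iterations ago, both learning rates are
#'   halved and the momentum is reset. Near convergence the guard fires
#'   repeatedly and anneals the rates toward zero.
#' @param plateau_tol Relative loss change below which (for 5 consecutive
#'   iterations) the run stops early; `0` disables.
#' @param init_dn_range Birefringence range of the random initialization.
#' @param seed Seed for initialization and batch shuffling.
#' @return List of class `recon_config`.
#' @export
recon_config <- function(n_iter = 120, lr_orientation = 3e-2,
                         lr_index = 3e-7, momentum = 0.9,
                         block_orientation = 10, block_index = 10,
                         w_orientation = 0.5, w_index = 1e5,
                         batch_size = NULL, patience = 10,
                         plateau_tol = 0, init_dn_range = c(0, 0.002),
                         seed = 1) {
  stopifnot(n_iter >= 1, lr_orientation > 0, lr_index > 0,
            momentum >= 0, momentum < 1, block_orientation >= 1,
            block_index >= 1, w_orientation >= 0, w_index >= 0)
  structure(as.list(environment()), class = "recon_config")
}

## Wrap updated angles back into their domains: psi mod 2*pi, and fold phi
## through the poles (phi -> 2*pi - phi flips are re-expressed by the
## equivalent (phi, psi + pi)).
wrap_angles <- function(phi, psi) {
  phi <- phi %% (2 * pi)
  over <- phi > pi
  psi[over] <- psi[over] + pi
  phi[over] <- 2 * pi - phi[over]
  list(phi = phi, psi = psi %% (2 * pi))
}

## Objective + gradient at a parameter point, shared by reconstruct().
recon_objective <- function(phi, psi, n_e, template, measured, geometry,
                            config, projections) {
  g <- template
  g$phi <- phi; g$psi <- psi; g$n_e <- n_e
  dg <- analytic_gradient(g, measured, geometry, projections)
  ro <- smooth_reg_orientation(phi, psi)
  rn <- smooth_reg_index(n_e)
  list(eps_i = dg$eps_i, reg_o = ro$value, reg_n = rn$value,
       grad_phi = dg$phi + config$w_orientation * ro$grad_phi,
       grad_psi = dg$psi + config$w_orientation * ro$grad_psi,
       grad_ne = dg$n_e + config$w_index * rn$grad)
}

#' Reconstruct the per-voxel index ellipsoids from measured projections
#'
#' Minimizes the intensity loss plus orientation/index smoothing
#' regularizers over all voxels' `(phi, psi, n_e)` by Nesterov-accelerated
#' gradient descent with analytical gradients, alternating stage-wise
#' between the orientation angles and the extraordinary index. The
#' absorption volume is not part of this optimization; see
#' [reconstruct_absorption()].
#'
#' @param measured A [projection_set()].
#' @param geometry The [acq_geometry()] of the measurement.
#' @param dims Grid dimensions `c(nx, ny, nz)` to reconstruct on.
#' @param config A [recon_config()].
#' @param init Optional [voxel_grid()] starting estimate; default a
#'   uniform-random grid drawn from `config$seed` (see
#'   [make_random_init()]).
#' @param truth Optional ground-truth [voxel_grid()]; adds per-iteration
#'   proximity traces.
#' @return Object of class `recon_result`: the final grid estimate, the
#'   per-iteration traces (`eps_i`, `reg_o`, `reg_n`, learning rates, and
#'   proximities when `truth` is given) and the configuration.
#' @export
reconstruct <- function(measured, geometry = measured$geometry,
                        dims = NULL, config = recon_config(),
                        init = NULL, truth = NULL) {
  if (is.null(init)) {
    if (is.null(dims)) stop("either dims or init must be given")
    init <- make_random_init(dims, n_o = geometry$n_o, d = geometry$d,
                             lambda = geometry$lambda,
                             dn_range = config$init_dn_range,
                             seed = config$seed)
  }
  dims <- init$dims
  phi <- init$phi; psi <- init$psi; n_e <- init$n_e
  v_phi <- array(0, dims); v_psi <- array(0, dims); v_ne <- array(0, dims)
  ne_lo <- geometry$n_o + min(config$init_dn_range)
  ne_hi <- geometry$n_o + max(config$init_dn_range)

  n_proj <- nrow(geometry$angles)
  batch <- config$batch_size
  full_batch <- is.null(batch) || batch >= n_proj
  cyc <- config$block_orientation + config$block_index

  lr_o <- config$lr_orientation
  lr_n <- config$lr_index
  mu <- config$momentum
  tr <- list(eps_i = numeric(0), reg_o = numeric(0), reg_n = numeric(0),
             lr_orientation = numeric(0), lr_index = numeric(0),
             prox_orientation = numeric(0), prox_index = numeric(0))
  backoffs <- 0L
  plateau_run <- 0L
  batch_rng <- NULL
  if (!full_batch) {
    batch_rng <- local({
      set.seed(config$seed + 1L)
      function(n) sample.int(n_proj, n)
    })
  }
  prev_stage <- ""

  for (it in seq_len(config$n_iter)) {
    stage <- if ((it - 1) %% cyc < config$block_orientation) {
      "orientation"
    } else {
      "index"
    }
    if (stage != prev_stage) {
      ## fresh momentum when the active parameter group changes
      v_phi[] <- 0; v_psi[] <- 0; v_ne[] <- 0
      prev_stage <- stage
    }
    projections <- if (full_batch) NULL else batch_rng(batch)

    ## look-ahead point (active group only)
    if (stage == "orientation") {
      y_phi <- phi + mu * v_phi; y_psi <- psi + mu * v_psi; y_ne <- n_e
    } else {
      y_phi <- phi; y_psi <- psi; y_ne <- n_e + mu * v_ne
    }
    ob <- recon_objective(y_phi, y_psi, y_ne, init, measured, geometry,
                          config, projections)
    if (!is.finite(ob$eps_i) ||
        any(!is.finite(ob$grad_phi)) || any(!is.finite(ob$grad_psi)) ||
        any(!is.finite(ob$grad_ne))) {
      stop("non-finite loss or gradient at iteration ", it)
    }
    if (stage == "orientation") {
      v_phi <- mu * v_phi - lr_o * ob$grad_phi
      v_psi <- mu * v_psi - lr_o * ob$grad_psi
      phi <- phi + v_phi
      psi <- psi + v_psi
      wr <- wrap_angles(phi, psi)
      phi <- wr$phi; psi <- wr$psi
    } else {
      v_ne <- mu * v_ne - lr_n * ob$grad_ne
      n_e <- pmin(pmax(n_e + v_ne, ne_lo), ne_hi)
    }

    tr$eps_i <- c(tr$eps_i, ob$eps_i)
    tr$reg_o <- c(tr$reg_o, ob$reg_o)
    tr$reg_n <- c(tr$reg_n, ob$reg_n)
    tr$lr_orientation <- c(tr$lr_orientation, lr_o)
    tr$lr_index <- c(tr$lr_index, lr_n)
    if (!is.null(truth)) {
      est <- init; est$phi <- phi; est$psi <- psi; est$n_e <- n_e
      pm <- proximity_metrics(est, truth)
      tr$prox_orientation <- c(tr$prox_orientation, pm$orientation)
      tr$prox_index <- c(tr$prox_index, pm$index_error)
    }

    ## divergence guard: sustained loss increase halves the rates
    n_tr <- length(tr$eps_i)
    if (n_tr > config$patience &&
        tr$eps_i[n_tr] > tr$eps_i[n_tr - config$patience]) {
      lr_o <- lr_o * 0.5
      lr_n <- lr_n * 0.5
      v_phi[] <- 0; v_psi[] <- 0; v_ne[] <- 0
      backoffs <- backoffs + 1L
      message(sprintf("iteration %d: loss increasing, learning rates halved",
                      it))
    }
    if (config$plateau_tol > 0 && n_tr > 1) {
      rel <- abs(tr$eps_i[n_tr] - tr$eps_i[n_tr - 1]) /
        max(tr$eps_i[n_tr - 1], .Machine$double.eps)
      plateau_run <- if (rel < config$plateau_tol) plateau_run + 1L else 0L
      if (plateau_run >= 5L) break
    }
  }

  est <- init
  est$phi <- phi; est$psi <- psi; est$n_e <- n_e
  structure(list(grid = est, trace = tr, config = config,
                 backoffs = backoffs, iterations = length(tr$eps_i)),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("Reconstruction: %d iterations, final loss %.4g\n",
              x$iterations, utils::tail(x$trace$eps_i, 1)))
  if (length(x$trace$prox_orientation)) {
    cat(sprintf("  orientation proximity %.4f, normalized index error %.4f\n",
                utils::tail(x$trace$prox_orientation, 1),
                utils::tail(x$trace$prox_index, 1)))
  }
  invisible(x)
}

#' Per-pixel isotropic transmission of a projection stack
#'
#' Element (1,1) of the synthesized Mueller matrix, i.e. the product of the
#' scalar voxel transmissions along each ray. Computed as a fixed weighted
#' sum of the 16 polarization images.
#'
#' @param ps A [projection_set()].
#' @return Array `(n_k, n_j, n_proj)`.
#' @export
transmission_images <- function(ps) {
  sm <- state_matrices()
  u <- solve(sm$A)[1, ]
  w <- solve(sm$G)[, 1]
  d <- dim(ps$intensities)
  out <- array(0, d[c(1, 2, 4)])
  raw <- ps$intensities / copol_norm()
  tab <- pol_set_table()
  for (l in 1:16) {
    a <- match(tab$analyzer[l], names(polarization_states()))
    g <- match(tab$generator[l], names(polarization_states()))
    out <- out + u[a] * w[g] * raw[, , l, ]
  }
  out
}

#' Reconstruct the absorption tomogram
#'
#' The scalar transmissions factor out of the retarder chain, so the
#' negative log of the per-pixel transmission is a straight-ray line
#' integral of the per-voxel absorption. That linear tomography problem is
#' solved by SIRT (simultaneous iterative reconstruction) with a
#' non-negativity constraint.
#'
#' @param measured A [projection_set()].
#' @param geometry The matching [acq_geometry()].
#' @param dims Grid dimensions to reconstruct on.
#' @param n_iter SIRT iterations.
#' @param relax Relaxation factor.
#' @param floor Transmission floor; non-positive pixels are clipped here
#'   with a warning.
#' @return Absorption array (attenuation per voxel path length), >= 0.
#' @export
reconstruct_absorption <- function(measured, geometry = measured$geometry,
                                   dims, n_iter = 100, relax = 1,
                                   floor = 1e-6) {
  tim <- transmission_images(measured)
  if (any(tim <= 0)) {
    warning("non-positive transmission pixels clipped to the floor")
  }
  b <- -log(pmax(tim, floor))
  ang <- angles_rad(geometry)
  d <- dim(tim)
  dims <- as.integer(dims)
  proj <- function(x) cpp_project_lines(x, dims, ang$alpha, ang$beta,
                                        d[1], d[2])
  back <- function(r) cpp_backproject_lines(r, dims, ang$alpha, ang$beta,
                                            d[1], d[2])
  row_sum <- proj(array(1, dims))        # samples per ray
  col_sum <- back(array(1, d))           # rays per voxel
  inv_row <- ifelse(row_sum > 0, 1 / row_sum, 0)
  inv_col <- ifelse(col_sum > 0, 1 / col_sum, 0)
  x <- array(0, dims)
  for (i in seq_len(n_iter)) {
    r <- (b - proj(x)) * inv_row
    x <- pmax(x + relax * back(r) * inv_col, 0)
  }
  x
}

#' Proximity of an estimate to the ground truth
#'
#' Orientation proximity is the mean absolute dot product between the
#' estimated and true c-axis unit vectors (absolute value: c and -c are
#' the same director); the index error is the mean absolute `n_e`
#' deviation normalized to the maximum birefringence.
#'
#' @param estimate,truth [voxel_grid()] objects of identical dimension.
#' @param mask Logical array selecting the voxels to average over; default
#'   the truth's sample support (birefringent or absorbing voxels), or all
#'   voxels if the truth has no support.
#' @param dn_max Normalization of the index error (default 0.002).
#' @return List with `orientation` (in `[0, 1]`, 1 = perfect) and
#'   `index_error` (0 = perfect).
#' @export
proximity_metrics <- function(estimate, truth, mask = NULL,
                              dn_max = 0.002) {
  if (!identical(estimate$dims, truth$dims)) stop("grid shapes differ")
  if (is.null(mask)) {
    mask <- (truth$n_e - truth$n_o) > 1e-9 | truth$absorption > 0
    if (!any(mask)) mask <- array(TRUE, truth$dims)
  }
  ce <- list(sin(estimate$phi) * cos(estimate$psi),
             sin(estimate$phi) * sin(estimate$psi), cos(estimate$phi))
  ct <- list(sin(truth$phi) * cos(truth$psi),
             sin(truth$phi) * sin(truth$psi), cos(truth$phi))
  dot <- abs(ce[[1]] * ct[[1]] + ce[[2]] * ct[[2]] + ce[[3]] * ct[[3]])
  list(orientation = mean(dot[mask]),
       index_error = mean(abs(estimate$n_e - truth$n_e)[mask]) / dn_max)
}
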