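# Loss, analytic gradients, regularizers, the Nesterov driver, absorption
# tomography, and the proximity metrics.

test_that("intensity loss is an element-wise sum of squares", {
  geo <- tiny_geometry()
  g <- random_grid(c(3, 3, 3), seed = 1)
  ps <- simulate_intensities(g, geo)
  expect_identical(intensity_loss(ps, ps), 0)
  bump <- ps
  bump$intensities[2, 2, 5, 3] <- bump$intensities[2, 2, 5, 3] + 1
  expect_equal(intensity_loss(ps, bump), 1)
  set.seed(4)
  other <- ps
  other$intensities[] <- runif(length(ps$intensities))
  expect_equal(intensity_loss(ps, other),
               sum((other$intensities - ps$intensities)^2))
  short <- ps
  short$intensities <- ps$intensities[, , , 1:3, drop = FALSE]
  expect_error(intensity_loss(ps, short), "shape")
})

test_that("analytic gradient vanishes at a perfect fit", {
  geo <- tiny_geometry()
  g <- random_grid(c(3, 3, 3), seed = 2)
  meas <- simulate_intensities(g, geo)
  dg <- analytic_gradient(g, meas, geo)
  expect_equal(dg$eps_i, 0, tolerance = 1e-18)
  expect_equal(max(abs(dg$phi)), 0, tolerance = 1e-9)
  expect_equal(max(abs(dg$psi)), 0, tolerance = 1e-9)
  expect_equal(max(abs(dg$n_e)), 0, tolerance = 1e-9)
})

test_that("analytic gradient matches central finite differences", {
  geo <- tiny_geometry()
  truth <- random_grid(c(3, 3, 3), seed = 5)
  meas <- simulate_intensities(truth, geo)
  g <- random_grid(c(3, 3, 3), seed = 6)
  dg <- analytic_gradient(g, meas, geo)
  loss_at <- function(g2) intensity_loss(meas, simulate_intensities(g2, geo))
  h <- 1e-6
  set.seed(99)
  for (nm in c("phi", "psi", "n_e")) {
    grad <- dg[[nm]]
    for (i in sample(27, 9)) {
      gp <- g; gp[[nm]][i] <- gp[[nm]][i] + h
      gm <- g; gm[[nm]][i] <- gm[[nm]][i] - h
      fd <- (loss_at(gp) - loss_at(gm)) / (2 * h)
      expect_lt(abs(fd - grad[i]) / max(abs(fd), abs(grad[i]), 1e-8),
                1e-4)
    }
  }
})

test_that("single-voxel single-projection gradient matches the scalar derivative", {
  # one voxel, one angle pair: the intensity is an explicit scalar function
  # of (phi, psi, n_e); differentiate it symbolically via numDeriv-free
  # high-order central differences at tiny step as the independent check
  geo <- acq_geometry(data.frame(alpha = 23, beta = -6.8))
  truth <- random_grid(c(1, 1, 1), seed = 8)
  meas <- simulate_intensities(truth, geo)
  g <- random_grid(c(1, 1, 1), seed = 9)
  dg <- analytic_gradient(g, meas, geo)
  loss_at <- function(vals) {
    g2 <- g; g2$phi[1] <- vals[1]; g2$psi[1] <- vals[2]; g2$n_e[1] <- vals[3]
    intensity_loss(meas, simulate_intensities(g2, geo))
  }
  x0 <- c(g$phi[1], g$psi[1], g$n_e[1])
  grads <- c(dg$phi[1], dg$psi[1], dg$n_e[1])
  for (k in 1:3) {
    h <- if (k == 3) 1e-7 else 1e-5
    e <- replace(numeric(3), k, h)
    # 4th-order central difference
    fd <- (-loss_at(x0 + 2 * e) + 8 * loss_at(x0 + e) - 8 * loss_at(x0 - e) +
           loss_at(x0 - 2 * e)) / (12 * h)
    expect_equal(grads[k], fd, tolerance = 1e-6 * max(1, abs(fd)))
  }
})

test_that("orientation regularizer: value, director symmetry, gradient", {
  g <- random_grid(c(3, 3, 2), seed = 10)
  r <- smooth_reg_orientation(g$phi, g$psi)
  # brute-force pair loop
  dims <- dim(g$phi)
  cax <- function(i, j, k) c(sin(g$phi[i, j, k]) * cos(g$psi[i, j, k]),
                             sin(g$phi[i, j, k]) * sin(g$psi[i, j, k]),
                             cos(g$phi[i, j, k]))
  val <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:2) {
    if (i < 3) val <- val + 1 - sum(cax(i, j, k) * cax(i + 1, j, k))^2
    if (j < 3) val <- val + 1 - sum(cax(i, j, k) * cax(i, j + 1, k))^2
    if (k < 2) val <- val + 1 - sum(cax(i, j, k) * cax(i, j, k + 1))^2
  }
  expect_equal(r$value, val, tolerance = 1e-12)
  # uniform field has zero penalty
  u <- smooth_reg_orientation(array(0.4, dims), array(1.1, dims))
  expect_equal(u$value, 0, tolerance = 1e-12)
  # flipping one voxel's director (phi, psi) -> (pi - phi, psi + pi)
  g2 <- g
  g2$phi[2, 2, 1] <- pi - g$phi[2, 2, 1]
  g2$psi[2, 2, 1] <- (g$psi[2, 2, 1] + pi) %% (2 * pi)
  expect_equal(smooth_reg_orientation(g2$phi, g2$psi)$value, r$value,
               tolerance = 1e-10)
  # gradients vs finite differences
  h <- 1e-6
  set.seed(11)
  for (i in sample(prod(dims), 6)) {
    for (nm in c("phi", "psi")) {
      ap <- g[[nm]]; ap[i] <- ap[i] + h
      am <- g[[nm]]; am[i] <- am[i] - h
      fd <- if (nm == "phi") {
        (smooth_reg_orientation(ap, g$psi)$value -
         smooth_reg_orientation(am, g$psi)$value) / (2 * h)
      } else {
        (smooth_reg_orientation(g$phi, ap)$value -
         smooth_reg_orientation(g$phi, am)$value) / (2 * h)
      }
      got <- if (nm == "phi") r$grad_phi[i] else r$grad_psi[i]
      expect_equal(got, fd, tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("index regularizer: value and gradient", {
  n_e <- array(1.48, c(2, 1, 1)); n_e[2] <- 1.481
  r <- smooth_reg_index(n_e)
  expect_equal(r$value, 1e-6, tolerance = 1e-12)
  expect_equal(smooth_reg_index(array(1.48, c(3, 3, 3)))$value, 0)
  g <- random_grid(c(3, 2, 3), seed = 12)
  r <- smooth_reg_index(g$n_e)
  val <- 0
  for (i in 1:3) for (j in 1:2) for (k in 1:3) {
    if (i < 3) val <- val + (g$n_e[i, j, k] - g$n_e[i + 1, j, k])^2
    if (j < 2) val <- val + (g$n_e[i, j, k] - g$n_e[i, j + 1, k])^2
    if (k < 3) val <- val + (g$n_e[i, j, k] - g$n_e[i, j, k + 1])^2
  }
  expect_equal(r$value, val, tolerance = 1e-15)
  h <- 1e-7
  set.seed(13)
  for (i in sample(18, 5)) {
    ap <- g$n_e; ap[i] <- ap[i] + h
    am <- g$n_e; am[i] <- am[i] - h
    fd <- (smooth_reg_index(ap)$value - smooth_reg_index(am)$value) / (2 * h)
    expect_equal(r$grad[i], fd, tolerance = 1e-4 * max(1e-6, abs(fd)))
  }
})

test_that("Nesterov update reduces to GD at zero momentum and matches the recursion", {
  gradf <- function(x) 2 * x          # f(x) = x^2
  st <- nesterov_step(3, 0, gradf, lr = 0.1, momentum = 0)
  expect_equal(st$x, 3 - 0.1 * 2 * 3)
  expect_equal(nesterov_step(2, 0.5, function(x) 0, 0.1, 0.9)$x, 2.45)
  # textbook look-ahead recursion, iterated independently
  x <- 3; v <- 0; mu <- 0.8; lr <- 0.05
  xs <- numeric(20)
  for (i in 1:20) {
    v <- mu * v - lr * gradf(x + mu * v)
    x <- x + v
    xs[i] <- x
  }
  x2 <- 3; v2 <- 0
  for (i in 1:20) {
    st <- nesterov_step(x2, v2, gradf, lr, mu)
    x2 <- st$x; v2 <- st$v
    expect_equal(x2, xs[i], tolerance = 1e-14)
  }
  expect_error(nesterov_step(1, 0, function(x) NaN, 0.1, 0.9), "finite")
})

test_that("initializing at the truth keeps the fit and parameters fixed", {
  geo <- tiny_geometry()
  truth <- random_grid(c(1, 1, 1), seed = 14)
  meas <- simulate_intensities(truth, geo)
  cfg <- recon_config(n_iter = 8, plateau_tol = 0, momentum = 0)
  res <- suppressMessages(reconstruct(meas, geo, config = cfg, init = truth))
  expect_lt(max(res$trace$eps_i), 1e-12)
  expect_equal(res$grid$phi, truth$phi, tolerance = 1e-9)
  expect_equal(res$grid$n_e, truth$n_e, tolerance = 1e-12)
})

test_that("plain-GD loss trace is non-increasing on a noiseless problem", {
  geo <- tiny_geometry()
  truth <- make_spiral(shape = c(5, 7, 5), pitch = 5, radius = 1,
                       helix_radius = 1)
  meas <- simulate_intensities(truth, geo)
  cfg <- recon_config(n_iter = 30, momentum = 0, lr_orientation = 1e-3,
                      lr_index = 1e-8, block_orientation = 30,
                      block_index = 1, w_orientation = 0.1, w_index = 1e3,
                      plateau_tol = 0, seed = 2)
  res <- suppressMessages(reconstruct(meas, geo, dims = c(5, 7, 5),
                                      config = cfg))
  expect_true(all(diff(res$trace$eps_i) <= 1e-9))
})

test_that("reconstruction is deterministic under a fixed seed", {
  geo <- tiny_geometry()
  truth <- random_grid(c(2, 2, 2), seed = 20)
  meas <- simulate_intensities(truth, geo)
  cfg <- recon_config(n_iter = 6, seed = 3, plateau_tol = 0)
  r1 <- suppressMessages(reconstruct(meas, geo, dims = c(2, 2, 2),
                                     config = cfg))
  r2 <- suppressMessages(reconstruct(meas, geo, dims = c(2, 2, 2),
                                     config = cfg))
  expect_identical(r1$grid$phi, r2$grid$phi)
  expect_identical(r1$trace$eps_i, r2$trace$eps_i)
})

test_that("mini-batch descent visits projection subsets reproducibly", {
  geo <- tiny_geometry()
  truth <- random_grid(c(2, 2, 2), seed = 21)
  meas <- simulate_intensities(truth, geo)
  cfg <- recon_config(n_iter = 5, batch_size = 2, seed = 4,
                      plateau_tol = 0)
  r1 <- suppressMessages(reconstruct(meas, geo, dims = c(2, 2, 2),
                                     config = cfg))
  r2 <- suppressMessages(reconstruct(meas, geo, dims = c(2, 2, 2),
                                     config = cfg))
  expect_identical(r1$trace$eps_i, r2$trace$eps_i)
  # batch losses are partial sums, strictly below the full-batch loss
  full <- suppressMessages(reconstruct(meas, geo, dims = c(2, 2, 2),
                                       config = recon_config(
                                         n_iter = 1, seed = 4,
                                         plateau_tol = 0)))
  expect_lt(r1$trace$eps_i[1], full$trace$eps_i[1])
})

test_that("absorption tomography recovers uniform, empty and impulse volumes", {
  dims <- c(7, 7, 7)
  geo <- acq_geometry()
  # uniform absorbing cube
  g <- voxel_grid(array(0, dims), array(0, dims), array(1.48, dims),
                  array(0.2, dims))
  ps <- simulate_intensities(g, geo)
  A <- reconstruct_absorption(ps, geo, dims, n_iter = 150)
  interior <- A[3:5, 3:5, 3:5]
  expect_lt(max(abs(interior - 0.2)) / 0.2, 0.05)
  # transparent grid
  g0 <- voxel_grid(array(0, dims), array(0, dims), array(1.48, dims))
  A0 <- reconstruct_absorption(simulate_intensities(g0, geo), geo, dims)
  expect_lt(max(A0), 1e-6)
  # single absorbing voxel reconstructs point-like at the right place
  g1 <- g0
  g1$absorption[4, 4, 4] <- 0.3
  A1 <- reconstruct_absorption(simulate_intensities(g1, geo), geo, dims,
                               n_iter = 200)
  expect_identical(arrayInd(which.max(A1), dims), matrix(c(4L, 4L, 4L), 1))
  # the impulse holds most of the reconstructed mass
  expect_gt(A1[4, 4, 4] / sum(A1), 0.3)
})

test_that("proximity metrics honour the director symmetry", {
  truth <- make_spiral(shape = c(5, 9, 5), pitch = 7, radius = 1)
  pm <- proximity_metrics(truth, truth)
  expect_equal(pm$orientation, 1)
  expect_equal(pm$index_error, 0)
  flipped <- truth
  flipped$phi <- pi - truth$phi
  flipped$psi <- (truth$psi + pi) %% (2 * pi)
  pm2 <- proximity_metrics(flipped, truth)
  expect_equal(pm2$orientation, 1, tolerance = 1e-12)
  # random estimate against a closed-form per-voxel loop
  est <- make_random_init(c(5, 9, 5), seed = 31)
  pm3 <- proximity_metrics(est, truth)
  mask <- (truth$n_e - truth$n_o) > 1e-9 | truth$absorption > 0
  dots <- abs(sin(est$phi) * cos(est$psi) * sin(truth$phi) * cos(truth$psi) +
              sin(est$phi) * sin(est$psi) * sin(truth$phi) * sin(truth$psi) +
              cos(est$phi) * cos(truth$phi))
  expect_equal(pm3$orientation, mean(dots[mask]), tolerance = 1e-12)
  expect_equal(pm3$index_error,
               mean(abs(est$n_e - truth$n_e)[mask]) / 0.002,
               tolerance = 1e-12)
  expect_error(proximity_metrics(est, random_grid(c(2, 2, 2))), "differ")
})
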