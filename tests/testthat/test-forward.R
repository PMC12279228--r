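# Straight-ray forward model: voxel traversal, matrix chains, intensities,
# shot noise.

test_that("axis-aligned rays traverse one grid column", {
  g <- random_grid(c(4, 5, 6))
  p <- ray_voxel_path(g, 0, 0, c(2, 3))
  expect_identical(nrow(p$voxels), 6L)
  expect_true(all(p$voxels[, "ix"] == 2))
  expect_true(all(p$voxels[, "iy"] == 3))
  expect_identical(p$voxels[, "iz"], 1:6)
  expect_equal(p$lengths, rep(g$d, 6))
})

test_that("opposite rotation reverses the ray through the mirrored pixel", {
  g <- random_grid(c(5, 5, 5))
  for (px in list(c(1, 2), c(3, 3), c(5, 4))) {
    fwd <- ray_voxel_path(g, 0, 0, px)$voxels
    rev <- ray_voxel_path(g, 180, 0, c(6 - px[1], px[2]))$voxels
    expect_identical(rev, fwd[nrow(fwd):1, , drop = FALSE])
  }
})

test_that("nearest-neighbour sampling matches fine-step ray marching", {
  g <- random_grid(c(5, 5, 5))
  alpha <- 14; beta <- 6.8
  got <- ray_voxel_path(g, alpha, beta, c(3, 2))$voxels
  # independent dense oracle: march the lab-frame ray at step d/10 and
  # record the entered voxel sequence
  a <- alpha * pi / 180; b <- beta * pi / 180
  Rj <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
               byrow = TRUE)
  Rk <- matrix(c(1, 0, 0, 0, cos(b), -sin(b), 0, sin(b), cos(b)), 3, 3,
               byrow = TRUE)
  Rs <- Rk %*% Rj
  lab <- function(t) c(3 - 3, 2 - 3, t)   # pixel (3,2) on a 5x5 raster
  seen <- matrix(0L, 0, 3)
  for (t in seq(-6, 6, by = 0.1)) {
    obj <- drop(t(Rs) %*% lab(t)) + 3     # voxel-center coordinates 1..5
    v <- round(obj)
    if (all(v >= 1 & v <= 5)) {
      if (nrow(seen) == 0 || any(seen[nrow(seen), ] != v)) {
        seen <- rbind(seen, as.integer(v))
      }
    }
  }
  # the unit-step sampler visits a subsequence of the dense entered-voxel
  # sequence, in the same order, and shares the dominant column
  pos <- apply(got, 1, function(v) {
    w <- which(seen[, 1] == v[1] & seen[, 2] == v[2] & seen[, 3] == v[3])
    if (length(w)) w[1] else NA_integer_
  })
  expect_false(any(is.na(pos)))
  expect_true(all(diff(pos) > 0))
})

test_that("projection of a transparent grid is the identity everywhere", {
  dims <- c(3, 4, 3)
  g <- voxel_grid(array(0.5, dims), array(1, dims), array(1.48, dims))
  M <- project_mueller(g, 37, -6.8)
  for (k in 1:3) for (j in 1:4) expect_equal(M[, , k, j], diag(4))
})

test_that("per-pixel chains match brute-force sequential multiplication", {
  g <- random_grid(c(3, 4, 3), seed = 7, with_absorption = TRUE)
  fac <- 2 * pi * g$d / g$lambda
  for (ab in list(c(0, 0), c(14, -6.8), c(118, 6.8))) {
    M <- project_mueller(g, ab[1], ab[2])
    a <- ab[1] * pi / 180; b <- ab[2] * pi / 180
    for (px in list(c(2, 3), c(1, 1), c(3, 4))) {
      path <- ray_voxel_path(g, ab[1], ab[2], px)$voxels
      expM <- diag(4)
      for (r in seq_len(nrow(path))) {
        v <- path[r, ]
        cax <- c(sin(g$phi[v[1], v[2], v[3]]) * cos(g$psi[v[1], v[2], v[3]]),
                 sin(g$phi[v[1], v[2], v[3]]) * sin(g$psi[v[1], v[2], v[3]]),
                 cos(g$phi[v[1], v[2], v[3]]))
        ph <- angle_to_c_axis(cax, a, b)
        th <- as.numeric(fast_axis_angle(cax, a, b))
        dl <- fac * (e_wave_index(g$n_o, g$n_e[v[1], v[2], v[3]], ph) - g$n_o)
        expM <- voxel_mueller(dl, th, exp(-g$absorption[v[1], v[2], v[3]])) %*%
          expM
      }
      expect_equal(M[, , px[1], px[2]], expM, tolerance = 1e-12)
    }
  }
})

test_that("voxel order along a ray matters unless the fast axes agree", {
  A <- voxel_mueller(0.4, 0.2); B <- voxel_mueller(0.9, 1.3)
  expect_gt(max(abs(A %*% B - B %*% A)), 1e-3)
  C <- voxel_mueller(0.9, 0.2)
  expect_equal(A %*% C, C %*% A, tolerance = 1e-12)
})

test_that("empty-grid intensities sit at the co/cross-polarized extremes", {
  dims <- c(3, 3, 3)
  g <- voxel_grid(array(0, dims), array(0, dims), array(1.48, dims))
  ps <- simulate_intensities(g, tiny_geometry())
  tab <- pol_set_table()
  co <- which(tab$generator == "RCP" & tab$analyzer == "RCP")
  cross <- which(tab$generator == "RCP" & tab$analyzer == "LCP")
  expect_equal(max(abs(ps$intensities[, , co, ] - 1)), 0)
  expect_equal(max(abs(ps$intensities[, , cross, ])), 0)
  expect_true(all(ps$intensities >= -1e-12 & ps$intensities <= 1 + 1e-12))
})

test_that("a uniform slab reproduces the retarder-between-polarizers formula", {
  # single-voxel-thick slab, uniform retarder with in-plane fast axis
  dims <- c(3, 3, 1)
  psi0 <- 0.7
  g <- voxel_grid(array(pi / 2, dims), array(psi0, dims),
                  array(1.482, dims))
  geo <- acq_geometry(data.frame(alpha = 0, beta = 0))
  ps <- simulate_intensities(g, geo)
  delta <- 2 * pi * g$d * (1.482 - 1.48) / g$lambda
  theta <- psi0   # at alpha = beta = 0 the fast axis is the azimuth
  tab <- pol_set_table()
  # textbook intensities (normalized to the co-polarized maximum):
  # LP0 -> LP45: (1 + sin(2*2theta') ...) closed form via Stokes algebra
  s_of <- function(nm) list(RCP = c(0, 0, 1), LCP = c(0, 0, -1),
                            LP0 = c(1, 0, 0), LP45 = c(0, 1, 0))[[nm]]
  B <- voxel_mueller(delta, theta)[2:4, 2:4]
  for (l in seq_len(16)) {
    sg <- s_of(tab$generator[l]); sa <- s_of(tab$analyzer[l])
    expected <- 0.5 * (1 + drop(sa %*% B %*% sg))
    expect_equal(ps$intensities[2, 2, l, 1], expected, tolerance = 1e-12)
  }
  # the classic crossed-circular-polarizer law: I = (1 +/- cos delta)/2
  co <- which(tab$generator == "RCP" & tab$analyzer == "RCP")
  cross <- which(tab$generator == "RCP" & tab$analyzer == "LCP")
  expect_equal(ps$intensities[2, 2, co, 1], (1 + cos(delta)) / 2,
               tolerance = 1e-12)
  expect_equal(ps$intensities[2, 2, cross, 1], (1 - cos(delta)) / 2,
               tolerance = 1e-12)
  # and the extracted cumulative parameters equal the slab's own
  r <- extract_retarder(synthesize_mueller(ps, 1)[, , 2, 2])
  expect_equal(r$delta, delta, tolerance = 1e-9)
  expect_equal(r$theta, theta, tolerance = 1e-9)
})

test_that("shot noise is Poisson-like, deterministic per seed, and bounded", {
  dims <- c(8, 8, 4)
  g <- voxel_grid(array(0, dims), array(0, dims), array(1.48, dims))
  geo <- acq_geometry(data.frame(alpha = c(0, 90), beta = c(0, 0)),
                      n_pixels = c(8, 8))
  ps <- simulate_intensities(g, geo)
  n1 <- add_shot_noise(ps, seed = 5)
  n2 <- add_shot_noise(ps, seed = 5)
  n3 <- add_shot_noise(ps, seed = 6)
  expect_identical(n1$intensities, n2$intensities)
  expect_false(identical(n1$intensities, n3$intensities))
  # zero pixels stay zero; the co-polarized plateau keeps its mean within
  # a few standard errors of 1/sqrt(full_well * n)
  tab <- pol_set_table()
  cross <- which(tab$generator == "RCP" & tab$analyzer == "LCP")
  co <- which(tab$generator == "RCP" & tab$analyzer == "RCP")
  expect_equal(max(abs(n1$intensities[, , cross, ])), 0)
  plateau <- n1$intensities[, , co, ]
  expect_equal(mean(plateau), 1,
               tolerance = 5 / sqrt(4095 * length(plateau)))
  expect_gt(sd(plateau), 0)
})

test_that("the RNG stream is untouched by seeded noise", {
  dims <- c(2, 2, 2)
  g <- voxel_grid(array(0, dims), array(0, dims), array(1.48, dims))
  ps <- simulate_intensities(g, tiny_geometry())
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(add_shot_noise(ps, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})
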