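## Uniaxial crystal optics: incidence-dependent e-wave index, geometric
## angles relative to the beam, and the per-voxel Mueller matrix.

#' Extraordinary-wave refractive index for oblique incidence
#'
#' A uniaxial medium refracts the extraordinary wave with an effective index
#' that depends on the angle `phi_angle` between the ray and the optic
#' (c-) axis: \deqn{n_E = \frac{n_o n_e}{\sqrt{n_o^2 \sin^2\varphi +
#' n_e^2 \cos^2\varphi}}.}
#' Along the c-axis (`phi_angle = 0`) no double refraction occurs and
#' `n_E = n_o`; perpendicular to it `n_E = n_e`.
#'
#' @param n_o Ordinary refractive index (> 0).
#' @param n_e Extraordinary refractive index (> 0).
#' @param phi_angle Angle between ray and c-axis, radians. Enters only
#'   through `sin^2`/`cos^2`, so the director symmetry (c and -c identical)
#'   is automatic.
#' @return Effective e-wave index, bracketed by `n_o` and `n_e`.
#' @export
e_wave_index <- function(n_o, n_e, phi_angle) {
  if (any(n_o <= 0) || any(n_e <= 0)) {
    stop("refractive indices must be positive")
  }
  n_o * n_e / sqrt(n_o^2 * sin(phi_angle)^2 + n_e^2 * cos(phi_angle)^2)
}

#' Rotation matrix between object and laboratory frames
#'
#' The sample is rotated by `alpha` about the vertical lab axis j and tilted
#' by `beta` about the transverse lab axis k; the beam travels along the
#' third lab axis p. The returned operator `R_s = R_k(beta) R_j(alpha)` maps
#' object-frame vectors into the lab frame. Both factors are standard
#' right-handed rotations; the lab triad is k = (1,0,0), j = (0,1,0),
#' p = (0,0,1).
#'
#' @param alpha Rotation angle about j, radians.
#' @param beta Tilt angle about k, radians.
#' @return Orthogonal 3x3 matrix with determinant +1.
#' @export
rotation_to_lab <- function(alpha, beta) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  r_j <- matrix(c(ca, 0, -sa,
                  0,  1,  0,
                  sa, 0,  ca), 3, 3)        # column-major: R_j(alpha)
  r_k <- matrix(c(1, 0, 0,
                  0, cb, sb,
                  0, -sb, cb), 3, 3)        # R_k(beta)
  r_k %*% r_j
}

#' Angle between the optic axis and the beam
#'
#' Computes `arccos(p . R_s c)` for the lab beam direction p = (0,0,1),
#' where `R_s` rotates the object-frame c-axis into the lab frame.
#'
#' @param c_axis Unit 3-vector of the c-axis in the object frame.
#' @param alpha,beta Tomographic rotation and tilt, radians.
#' @return Angle in `[0, pi]`. Downstream use is through `sin^2`/`cos^2`
#'   only, which folds c and -c onto the same physics.
#' @export
angle_to_c_axis <- function(c_axis, alpha, beta) {
  stopifnot(length(c_axis) == 3)
  if (abs(sum(c_axis^2) - 1) > 1e-8) {
    stop("c_axis must be a unit vector")
  }
  cl <- rotation_to_lab(alpha, beta) %*% c_axis
  acos(max(-1, min(1, cl[3])))
}

#' Fast-axis angle in the detector plane
#'
#' Projects the lab-frame c-axis onto the plane transverse to the beam,
#' renormalizes, and measures its angle from the lab k axis with a
#' two-argument arctangent folded into `[0, pi)`. The fold is harmless: the
#' angle enters every Mueller element only through `cos(2theta)` and
#' `sin(2theta)`.
#'
#' When the c-axis is (numerically) parallel to the beam the projection
#' vanishes and the angle is physically irrelevant because the voxel
#' retardance is zero there; the function then returns 0 with attribute
#' `degenerate = TRUE`.
#'
#' @inheritParams angle_to_c_axis
#' @param tol Squared-norm threshold below which the projection counts as
#'   degenerate.
#' @return Fast-axis angle in `[0, pi)`.
#' @export
fast_axis_angle <- function(c_axis, alpha, beta, tol = 1e-12) {
  stopifnot(length(c_axis) == 3)
  if (abs(sum(c_axis^2) - 1) > 1e-8) {
    stop("c_axis must be a unit vector")
  }
  cl <- rotation_to_lab(alpha, beta) %*% c_axis
  rho2 <- cl[1]^2 + cl[2]^2
  if (rho2 < tol) {
    return(structure(0, degenerate = TRUE))
  }
  theta <- atan2(cl[2], cl[1]) %% pi
  structure(theta, degenerate = FALSE)
}

#' Mueller matrix of one linearly birefringent voxel
#'
#' A voxel acts as a linear retarder of retardance `delta`, fast axis
#' `theta` and scalar transmission `t_lr`:
#' \deqn{M = t_{LR}\, M_R(-\theta)\, M_{LR0}(\delta)\, M_R(\theta)}
#' expanded to the closed 4x4 form used throughout the package. Element
#' `[1,1]` equals `t_lr`; for `t_lr = 1` the lower-right 3x3 block is a
#' rotation of the Poincare sphere, so the degree of polarization is
#' preserved (pure retarder).
#'
#' @param delta Retardance, radians.
#' @param theta Fast-axis angle, radians.
#' @param t_lr Scalar transmission in (0, 1].
#' @return 4x4 Mueller matrix.
#' @export
voxel_mueller <- function(delta, theta, t_lr = 1) {
  stopifnot(is.finite(delta), is.finite(theta), t_lr > 0, t_lr <= 1)
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  cd <- cos(delta);     sd <- sin(delta)
  t_lr * matrix(c(
    1, 0, 0, 0,
    0, c2^2 + cd * s2^2, (1 - cd) * c2 * s2, sd * s2,
    0, (1 - cd) * c2 * s2, cd * c2^2 + s2^2, -c2 * sd,
    0, -sd * s2, c2 * sd, cd), 4, 4)
}

#' Mueller matrix of an ideal optical rotator
#'
#' Rotates the linear-polarization components of a Stokes vector by `theta`;
#' used to express a rotated retarder as
#' `M_R(-theta) %*% mueller_retarder0(delta) %*% M_R(theta)`.
#'
#' @param theta Rotation angle, radians.
#' @return 4x4 Mueller matrix.
#' @export
mueller_rotator <- function(theta) {
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  matrix(c(1, 0, 0, 0,
           0, c2, s2, 0,
           0, -s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Mueller matrix of an unrotated linear retarder
#'
#' Fast axis along the lab k axis; retardance `delta` mixes the 45-degree
#' linear and circular Stokes components.
#'
#' @param delta Retardance, radians.
#' @return 4x4 Mueller matrix.
#' @export
mueller_retarder0 <- function(delta) {
  cd <- cos(delta); sd <- sin(delta)
  matrix(c(1, 0, 0, 0,
           0, 1, 0, 0,
           0, 0, cd, sd,
           0, 0, -sd, cd), 4, 4, byrow = TRUE)
}

#' Poincare-sphere Stokes vectors of the four measurement states
#'
#' The polarization scheme uses two circular states (RCP, LCP, the sphere
#' poles) and two linear states (LP0, LP45, on the equator). Returned as a
#' named list of reduced Stokes 3-vectors `(s1, s2, s3)`.
#'
#' @return Named list of unit 3-vectors.
#' @export
polarization_states <- function() {
  list(RCP  = c(0, 0, 1),
       LCP  = c(0, 0, -1),
       LP0  = c(1, 0, 0),
       LP45 = c(0, 1, 0))
}

#' Mueller matrix of a polarization state generator or analyzer
#'
#' An ideal homogeneous polarizer for Poincare state `s` has Mueller matrix
#' `0.5 * rbind(c(1, s), cbind(s, s %o% s))`. As a generator it turns the
#' unpolarized source `S = (1,0,0,0)` into the fully polarized state
#' `(1, s)/2`; as an analyzer the same matrix projects onto that state, so
#' crossed circular states extinguish exactly and a matched pair on an empty
#' path transmits the co-polarized maximum.
#'
#' @param state One of `"RCP"`, `"LCP"`, `"LP0"`, `"LP45"`.
#' @param role `"generator"` or `"analyzer"` (same matrix; the argument
#'   documents intent and validates usage).
#' @return 4x4 Mueller matrix.
#' @export
pol_state_mueller <- function(state, role = c("generator", "analyzer")) {
  role <- match.arg(role)
  states <- polarization_states()
  if (!state %in% names(states)) {
    stop("unknown polarization state: ", state)
  }
  s <- states[[state]]
  0.5 * rbind(c(1, s), cbind(s, outer(s, s)))
}

#' The 16 generator/analyzer polarization sets
#'
#' Every combination of the four states in the generator and analyzer, in
#' the fixed order used by all intensity arrays: the analyzer index varies
#' fastest, i.e. set `l = (g - 1) * 4 + a` pairs generator `g` with
#' analyzer `a` over the state order RCP, LCP, LP0, LP45.
#'
#' @return data.frame with columns `set`, `generator`, `analyzer`.
#' @export
pol_set_table <- function() {
  states <- names(polarization_states())
  data.frame(set = 1:16,
             generator = rep(states, each = 4),
             analyzer = rep(states, times = 4),
             stringsAsFactors = FALSE)
}

## 4 x 4 x 16 arrays of generator / analyzer matrices in pol-set order,
## used by the compiled forward model.
pol_set_matrices <- function() {
  tab <- pol_set_table()
  gen <- array(0, c(4, 4, 16))
  ana <- array(0, c(4, 4, 16))
  for (l in 1:16) {
    gen[, , l] <- pol_state_mueller(tab$generator[l], "generator")
    ana[, , l] <- pol_state_mueller(tab$analyzer[l], "analyzer")
  }
  list(generator = gen, analyzer = ana)
}

#' Retardance of one voxel
#'
#' `delta = 2 pi d (n_E - n_o) / lambda`, with `d` the ray path length
#' through the voxel and `lambda` the wavelength (same length units).
#'
#' @inheritParams e_wave_index
#' @param d Path length through the voxel.
#' @param lambda Wavelength.
#' @return Retardance in radians (sign follows `n_e - n_o`).
#' @export
voxel_retardance <- function(n_o, n_e, phi_angle, d, lambda) {
  2 * pi * d * (e_wave_index(n_o, n_e, phi_angle) - n_o) / lambda
}

## c-axis unit vector from polar/azimuthal angles (object frame).
c_axis_vector <- function(phi, psi) {
  c(sin(phi) * cos(psi), sin(phi) * sin(psi), cos(phi))
}
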