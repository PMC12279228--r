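---
title: "Reconstructing 3D birefringence from polarization-resolved projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D birefringence from polarization-resolved projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical model

Many biological tissues — collagen-rich bone and connective tissue, nerve
fiber bundles, muscle — are optically uniaxial at the voxel scale: aligned
nanoscale fibrils make the refractive index depend on polarization, with a
single optic axis (the *c-axis*) along the dominant fiber direction.
`muellertomo` models every voxel of a volume as a uniaxial index ellipsoid
described by three free parameters: the polar and azimuthal angles
$(\phi, \psi)$ of the c-axis in the object frame and the extraordinary
index $n_e$. The ordinary index $n_o$ is a single known constant, matched
to the immersion liquid (default 1.48), and is never optimized.

A ray crossing a voxel at angle $\varphi$ to the c-axis sees the e-wave
index

$$n_E = \frac{n_o n_e}{\sqrt{n_o^2 \sin^2\varphi + n_e^2 \cos^2\varphi}},$$

so the voxel acts as a linear retarder with retardance
$\delta = 2\pi d\,(n_E - n_o)/\lambda$ ($d$ = path length through the
voxel, $\lambda$ = wavelength) and fast axis $\theta$, the angle of the
projected c-axis in the detector plane. Its Mueller matrix is the standard
rotated linear retarder

$$M = t_{LR}\, M_R(-\theta)\, M_{LR0}(\delta)\, M_R(\theta),$$

with a scalar transmission $t_{LR} = e^{-A}$ carrying the per-voxel
absorption $A$ (Beer–Lambert attenuation per voxel path length — the
functional link between $A$ and $t_{LR}$ is a package choice; any
monotone parameterization of a scalar loss factors out of the retarder
algebra identically).

The sample is rotated about two axes — rotation $\alpha$ about the
vertical axis $j$ and tilt $\beta$ about the transverse axis $k$; the
operator $R_s = R_k(\beta) R_j(\alpha)$ (standard right-handed rotation
matrices; the beam runs along the third lab axis $p$) maps object-frame
vectors into the lab. Two axes are essential: with a single rotation axis
the out-of-plane component of the c-axis is not identifiable. The default
scan uses $\alpha \in \{0°, 14°, \ldots, 350°\}$ at
$\beta \in \{0°, \pm 6.8°\}$, i.e. 78 projections.

One printed formula needs an interpretation: the fast-axis angle is
defined through the projection of the rotated c-axis onto the transverse
plane, and that projected vector must be renormalized before any inverse
trigonometry (as printed, the arccosine of an unnormalized dot product is
ill-defined). The package recovers $\theta$ with a two-argument
arctangent of the transverse components, which handles quadrants and
normalization at once; since only $2\theta$ enters the Mueller matrix,
$\theta$ is reported modulo $\pi$. When the c-axis is parallel to the
beam the projection vanishes; the retardance is exactly zero there, so
the convention $\theta = 0$ (flagged) is physically inert.

## Forward model

Light is assumed ballistic: straight parallel rays, one ray per detector
pixel, no refraction, double refraction, scattering or diffraction. This
is the standard regime for index-matched, weakly birefringent samples
($|n_e - n_o| \lesssim 10^{-2}$; the `voxel_grid()` constructor enforces
that bound).

Each ray is sampled at a fixed step of one voxel size along the beam with
nearest-neighbour lookup of the rotated grid; every in-grid sample
contributes one retarder matrix with constant path length $d$. The step
count parity is matched to the grid so that axis-aligned samples coincide
with voxel centers. The per-pixel sample matrix is the ordered product of
the per-sample matrices — Mueller matrices do not commute, so the voxel
nearest the sensor is the leftmost factor. An alternative would be exact
chord-length weighting per traversed voxel (Siddon-style); the fixed-step
convention was chosen because it keeps one matrix per sample with a
common $d$, keeps the loss piecewise-smooth in the parameters, and its
discretization error is bounded in the tests against a dense ray-marching
oracle at step $d/10$.

Sixteen polarization sets measure each projection: every pairing of the
four states RCP, LCP, LP0, LP45 (two Poincaré poles, two equator points)
in the generator and analyzer. Both are modeled as ideal homogeneous
polarizers $\tfrac12 \begin{pmatrix} 1 & s^\top \\ s & s s^\top
\end{pmatrix}$ for Poincaré vector $s$, applied to the unpolarized source
$S = (1,0,0,0)^\top$. All intensities are reported relative to the
co-polarized empty-path maximum, so a matched pair with no sample reads
exactly 1 and crossed circular states read exactly 0.

Shot noise emulates a 12-bit camera: the stack is scaled so its global
maximum maps to 4095 counts, Poisson-sampled, and rescaled. The noise is
seeded and leaves the session RNG untouched.

## The inverse problem

Reconstruction minimizes

$$\varepsilon^I = \sum_{i,l,k,j} \left(\hat I_{li}(k,j) -
I_{li}(k,j)\right)^2$$

over all voxels' $(\phi, \psi, n_e)$, plus two smoothing penalties. The
gradient is analytical: for voxel $p$ on a ray the chain rule keeps the
products of the matrices after ($O$) and before ($L$) the voxel fixed,
so each intensity contributes
$2(\hat I - I)\, q^\top \left(\partial_\theta M\, \partial_u \theta +
\partial_\delta M\, \partial_u \delta\right) v$ with
$q^\top = S^\top M^{PSA} O$ and $v = L\, M^{PSG} S$; terms for voxels off
the ray vanish. The prefix/suffix vectors are cached per ray in compiled
code, which makes a full-gradient iteration on the validation phantom a
fraction of a second. One numerical subtlety: the chain factor
$\partial n_E / \partial \varphi$ contains a $1/\sin\varphi$ from the
arccosine that cancels analytically; the implementation differentiates
$n_E$ with respect to $\cos\varphi$ directly, so the gradient is finite
at all orientations. Correctness is pinned by finite-difference tests at
relative error $10^{-4}$ over all three parameter groups.

### Regularizers

The supplementary material describing the original regularizers is not
public, so the package uses the simplest forms with the stated
properties, both over 6-connected neighbour pairs:

* orientation: $\sum_{\langle v,w \rangle} \left(1 - (c_v \cdot
  c_w)^2\right)$ — the square makes it a *director* penalty, invariant
  under $c \to -c$ of any voxel, zero iff neighbours are parallel or
  antiparallel;
* index: $\sum_{\langle v,w \rangle} (n_{e,v} - n_{e,w})^2$.

Their weights (`w_orientation = 0.5`, `w_index = 1e5`) were set once by a
line search on the validation phantom so that each term is of order
1–10% of the initial intensity loss; the large index weight only
compensates the $10^{-3}$ scale of birefringence differences.

### Optimizer

Nesterov-accelerated gradient descent with look-ahead gradient
evaluation, momentum 0.9. With momentum 0 the update reduces exactly to
plain gradient descent, which the tests exploit. Because the retardance
is roughly $2\pi d/\lambda \approx 236$ times more sensitive to $n_e$
than the geometry is to the angles, the two groups get separate learning
rates (defaults $3\times10^{-2}$ and $3\times10^{-7}$, again from a
one-time phantom line search) and are optimized stage-wise: 10
iterations of the orientation pair, then 10 of the index, repeating.
Momentum buffers are reset at stage boundaries. The angle pair is wrapped
back into its domain after every step ($\psi$ modulo $2\pi$; $\phi$
folded through the poles with the equivalent $\psi + \pi$). Note the
gimbal degeneracy: at $\phi \approx 0$ the azimuth $\psi$ is
unidentifiable; the director regularizer and the stage-wise alternation
are what keeps those voxels tame.

A divergence guard watches the loss trace: whenever the current loss
exceeds its value `patience` (default 10) iterations earlier, both rates
are halved and momentum is reset. Early on this catches genuine
overshoot; near convergence it fires repeatedly and anneals the rates,
which is what settles the iterate — with the guard disabled the loss
oscillates indefinitely at these rates. An optional plateau criterion
(relative change below `plateau_tol` for 5 consecutive iterations) can
stop runs early; it is off by default so iteration counts are exactly
reproducible. `batch_size` enables stochastic mini-batches over
projections (seeded); the default uses all projections, i.e.
deterministic full-batch descent. Hard NaN in loss or gradient aborts
with a diagnostic.

The default iteration budget is 120. The initialization is
uniform-random per voxel ($\phi \in [0,\pi]$, $\psi \in [0, 2\pi)$,
$n_e - n_o \in [0, 0.002]$), drawn from a seed, and $n_e$ is clamped to
the initialization range during optimization.

### Absorption

The scalar transmissions factor out of the retarder chain
(element $(1,1)$ of the per-pixel matrix is exactly $\prod t_{LR}$), so
absorption decouples from the polarimetric unknowns: $-\log$ of the
per-pixel transmission is a straight-ray line integral of $A$. That
linear problem is solved separately by SIRT with a non-negativity clamp,
reusing the same ray sampler as the forward model. Non-positive
transmission pixels (possible under noise) are clipped at a floor with a
warning. Nothing in the paper's description requires joint optimization,
and the decoupling is exact under the scalar-loss model.

## The validation phantom

`make_spiral()` builds the ground truth used throughout the tests: a
tube of radius 3 voxels wound as a single right-handed helical pitch of
22 voxels inside a 15 × 25 × 15 grid, c-axis everywhere tangent to the
helix, birefringence ramping linearly along the arc over
$[0.001, 0.002]$ and absorption over $[0.1, 0.3]$; the background is
index-matched ($n_e = n_o$) and transparent. The helix axis runs along
the long grid dimension and the helix radius defaults to the largest
value that keeps the tube inside the cross-section. The exact spatial
profile of the ramps and the helix radius are package choices (only the
ranges and "gradual variation" are prescribed); foreground membership is
by Euclidean distance from the voxel center to the densely sampled
continuous centerline.

What the phantom emulates: spatially curving anisotropy with
out-of-plane components, realistic birefringence and absorption levels,
12-bit shot noise, and the full 78-projection dual-axis scan. What it
does not: refraction and lensing at sample boundaries, depolarization,
diattenuation, misalignment of the goniometer, and partial-volume
effects — so passing recovery tests demonstrates the correctness of the
model and optimizer, not robustness to those experimental
imperfections.

## Problem sizes in the tests

The test-suite and acceptance runs use a reduced phantom
(9 × 15 × 9, pitch 13, radius 2, same parameter ranges, same
78-projection geometry, shot noise on) so that a single reconstruction
takes well under a minute on one core; four reconstructions from
different random initializations back the seed-robustness check. At this
scale a converged run reaches mean orientation proximity
$|c_{est} \cdot c_{true}| \approx 0.95$ over foreground voxels and mean
normalized index error $\approx 0.11$; runs from different seeds agree
in final loss to a fraction of a percent. Gradient checks use 3 × 3 × 3
grids over a 6-projection geometry, where central finite differences are
cheap and well-conditioned.

## Known limitations

* The cumulative matrix of a thick, twisted sample is generally not a
  pure linear retarder; `extract_retarder()` reports the nearest
  retarder interpretation and flags pixels whose matrices depart from
  the retarder form instead of applying a full polar decomposition.
* Retardance maps are reported on the principal branch $[0, \pi]$; no
  spatial phase unwrapping is attempted.
* Only one matrix per unit-step sample is used along oblique rays; exact
  chord lengths differ by up to $\sqrt{3}$, a discretization the tests
  bound but do not remove.
* No diattenuation, depolarization or biaxial anisotropy in the voxel
  model, and no GPU path.
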