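# muellertomo

Tomographic Mueller-matrix polarimetry in R: simulate
polarization-resolved intensity projections of a voxelized, uniaxially
birefringent volume, and reconstruct each voxel's index ellipsoid — the
optic-axis orientation (ϕ, ψ) and the extraordinary refractive index
n_e — from such projections.

The intended users are microscopists and image-analysis researchers
working with birefringent biological materials (collagen in bone and
connective tissue, nerve and muscle fibers), where the nanoscale fiber
orientation is not directly resolvable but leaves a polarization
fingerprint. Conventional polarized-light microscopy reduces a sample to
a 2D map of cumulative retardance; this package implements the
tomographic extension that recovers the full 3D anisotropy field from
intensity-only measurements at dual-axis rotation/tilt angles.

## Model

Each voxel is a uniaxial index ellipsoid with c-axis
c = (sinϕ cosψ, sinϕ sinψ, cosϕ) and indices (n_o, n_e). A ray at angle
φ to the c-axis sees the e-wave index

    n_E = n_o n_e / sqrt(n_o² sin²φ + n_e² cos²φ)

and the voxel acts as a linear retarder, δ = 2πd(n_E − n_o)/λ, with fast
axis θ (the projected c-axis in the detector plane) and Mueller matrix
t_LR · M_R(−θ) M_LR0(δ) M_R(θ). A projection at rotation/tilt (α, β)
chains the matrices of all voxels along each ballistic ray,

    M_(α,β)(k, j) = ∏_p M^p,        Î_l = Sᵀ M_PSA,l M_(α,β) M_PSG,l S,

measured through 16 generator/analyzer polarization sets (RCP, LCP, LP0,
LP45 on both sides). Reconstruction minimizes the squared intensity
misfit ε^I plus director-symmetric orientation and index smoothing
penalties, by Nesterov-accelerated gradient descent with analytical
gradients, alternating stage-wise between (ϕ, ψ) and n_e. Absorption
decouples (it is the (1,1) element of the per-pixel matrix) and is
reconstructed separately by SIRT on −log transmission. The methods
vignette (`vignettes/birefringence-tomography.Rmd`) derives all of this
and records the numerical choices.

## Worked example

Simulate the helical validation phantom at the full 78-projection
dual-axis scan with 12-bit shot noise, then reconstruct it from a random
initialization:

```r
library(muellertomo)

truth <- make_spiral(shape = c(9, 15, 9), pitch = 13, radius = 2)
geometry <- acq_geometry()
ds <- make_dataset(truth, geometry, noise = TRUE, seed = 11)
ds$projections
#> Projection set: 78 projections x 16 polarization sets, 9 x 15 px

res <- reconstruct(ds$projections, geometry, dims = c(9, 15, 9),
                   config = recon_config(seed = 1), truth = truth)
res
#> Reconstruction: 120 iterations, final loss 7599
#>   orientation proximity 0.9547, normalized index error 0.1049

absorption <- reconstruct_absorption(ds$projections, geometry, c(9, 15, 9))
round(range(absorption), 3)
#> [1] 0.000 0.302

retardance_map(ds$projections, 1)
#> Retardance map at alpha = 0, beta = 0 deg: delta in [0.00223, 1.72] rad
```

The orientation proximity is the mean |c_est · c_true| over foreground
voxels (1 = perfect, and invariant to the physically meaningless c → −c
flip); the index error is the mean |n_e| deviation normalized to the
maximum birefringence 0.002. Here the c-axis field is recovered to ~0.95
and the birefringence to ~10% of its full scale despite the shot noise;
the recovered absorption spans the phantom's [0.1, 0.3] range (its
minimum is the transparent background). During the run the optimizer
occasionally reports `loss increasing, learning rates halved` — that is
the divergence guard annealing the step sizes.

A command-line wrapper for the simulate/reconstruct/analyze pipeline is
installed at `inst/scripts/muellertomo`:

```sh
Rscript inst/scripts/muellertomo simulate --config run.yaml --seed 1
```

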