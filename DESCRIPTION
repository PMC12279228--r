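Package: muellertomo
Title: Tomographic Mueller-Matrix Polarimetry and 3D Birefringence
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates polarization-resolved intensity projections of a
    voxelized uniaxially birefringent volume using Mueller-matrix optics
    under a ballistic straight-ray model, and reconstructs the per-voxel
    index ellipsoid (optic-axis polar and azimuthal angles and the
    extraordinary refractive index) from such projections by regularized
    Nesterov-accelerated gradient descent with analytical gradients.
    Includes a helical validation phantom generator, shot-noise
    simulation for 12-bit cameras, absorption tomography, and extraction
    of cumulative retardance and fast-axis maps from sets of sixteen
    polarization-resolved images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
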