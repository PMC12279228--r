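# Shared fixtures, built in code. The heavy spiral-recovery runs are
# computed lazily once per session and cached for every test that needs
# them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# small 6-projection geometry used by cheap forward/gradient tests
tiny_geometry <- function() {
  acq_geometry(data.frame(alpha = c(0, 60, 120, 180, 240, 300),
                          beta = c(0, -6.8, 6.8, 0, -6.8, 6.8)))
}

random_grid <- function(shape = c(3, 3, 3), seed = 3, with_absorption = FALSE) {
  g <- make_random_init(shape, seed = seed)
  if (with_absorption) {
    set.seed(seed + 100)
    g$absorption <- array(runif(prod(shape), 0, 0.3), shape)
  }
  g
}

# reduced helical phantom with 12-bit shot noise at the full 78-projection
# dual-axis scan, plus reconstructions from several random initializations
recovery_fixture <- function() {
  cached("recovery", {
    truth <- make_spiral(shape = c(9, 15, 9), pitch = 13, radius = 2)
    geometry <- acq_geometry()
    ds <- make_dataset(truth, geometry, noise = TRUE, seed = 11)
    runs <- lapply(1:4, function(s) {
      suppressMessages(reconstruct(
        ds$projections, geometry, dims = c(9, 15, 9),
        config = recon_config(seed = s), truth = truth))
    })
    list(truth = truth, geometry = geometry, measured = ds$projections,
         runs = runs)
  })
}
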