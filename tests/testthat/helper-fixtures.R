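# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

grid32 <- function() volumeGrid(c(32L, 32L, 32L), 1.36)

geom32 <- function(nAngles = 16L)
  acquisitionGeometry(nAngles = nAngles, detectorBins = c(32L, 32L),
                      binSize = 1.36)

geom64 <- function(nAngles = 32L)
  acquisitionGeometry(nAngles = nAngles, detectorBins = c(64L, 64L),
                      binSize = 0.68)

phantom32 <- function() fixture("phantom32", function()
  generatePhantom(5, grid = grid32()))

phantom64 <- function() fixture("phantom64", function() generatePhantom(1))

# Noisy two-window data and NAC initial estimates for the default phantom.
initEstimates64 <- function() fixture("initEstimates64", function() {
  ph <- phantom64()
  noisy <- addPoissonNoise(projectPhantom(ph, geom64()), 4e6, seed = 2)
  init <- reconstructInitialEstimates(noisy,
    scatterConfig = reconConfig(4, 5, useAttenuation = FALSE),
    photoConfig = reconConfig(8, 2, useAttenuation = FALSE))
  list(phantom = ph, noisy = noisy, init = init)
})

# Coordinate arrays for a grid (world cm, voxel centers).
coordArrays <- function(shape, vox) {
  x <- (seq_len(shape[1]) - 1 - (shape[1] - 1) / 2) * vox
  y <- (seq_len(shape[2]) - 1 - (shape[2] - 1) / 2) * vox
  z <- (seq_len(shape[3]) - 1 - (shape[3] - 1) / 2) * vox
  list(X = array(rep(x, times = shape[2] * shape[3]), shape),
       Y = array(rep(rep(y, each = shape[1]), times = shape[3]), shape),
       Z = array(rep(z, each = shape[1] * shape[2]), shape))
}
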