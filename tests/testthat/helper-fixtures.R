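# Shared fixtures: a coarse phantom and a small noiseless acquisition,
# built once per test run. Coarse grids keep the suite fast; the phantom
# defaults (0.44 mm, 25 phases) are exercised separately where they matter.

coarseSpec <- PhantomSpec(spacing = 1.5, nPhases = 8L)
coarseChi <- makePhantomCine(coarseSpec)

staticSpec <- PhantomSpec(spacing = 1.5, nPhases = 4L, contractionFrac = 0)
staticChi <- makePhantomCine(staticSpec)

# small axis-aligned frame grid centred on the heart
testFrameGrid <- function(npx = 24L, inPlane = 2, thickness = 6,
                          offset = c(0, 0, 0), directions = diag(3)) {
    og <- offset - directions[, 1] * inPlane * (npx - 1) / 2 -
        directions[, 2] * inPlane * (npx - 1) / 2
    VoxelGrid(c(npx, npx, 1L), c(inPlane, inPlane, thickness),
              origin = og, directions = directions)
}

# simulate a small multi-stack acquisition from a phantom cine
testSim <- function(chi, spec, nStacks = 2L, nSlices = 4L,
                    framesPerSlice = 8L, noiseSd = 0, seed = 1L,
                    traj = NULL) {
    geoms <- makeStackGeometries(nStacks, nSlices, fovMm = 64)
    simulateFrames(chi, geoms, traj, framesPerSlice = framesPerSlice,
                   noiseSd = noiseSd, seed = seed, spec = spec)
}

# synthetic uniformly-sampled pulsatile frame series for heart-rate tests
pulsatileSeries <- function(rateBpm, nFrames = 96L, dt = 0.072, npx = 12L,
                            noiseSd = 0, seed = 1L) {
    set.seed(seed)
    grid <- testFrameGrid(npx)
    amp <- matrix(runif(npx * npx, 0.2, 1), npx, npx)
    lapply(seq_len(nFrames), function(k) {
        t <- (k - 1) * dt
        px <- 1 + amp * 0.3 * sin(2 * pi * rateBpm / 60 * t) +
            matrix(rnorm(npx * npx, 0, noiseSd), npx, npx)
        FrameImage(pmax(px, 0), grid, time = t, slice = 1L, stack = 1L)
    })
}

expectTransformsEqual <- function(a, b, tolMm = 1e-6, tolDeg = 1e-6) {
    expect_lt(max(abs(a@translation - b@translation)), tolMm)
    expect_lt(max(abs(a@rotation - b@rotation)), tolDeg)
}
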