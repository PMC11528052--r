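# shared fixtures built in code

# geometry of the elevational scanner used across SAFT tests
stdGeometry <- function(n0 = 300) {
  ScanGeometry(lf = 20, w = 8, dz = 0.1, fs = 40e6, c = 1.5, n0 = n0)
}

# defocused three-target stack (targets 5, 7.5, 10 mm beyond focus)
defocusedStack <- function(noiseSigma = 0.01, seed = 7) {
  g <- stdGeometry()
  tg <- data.frame(depth_mm = c(25, 27.5, 30), elev_mm = c(5, 10, 15),
                   amplitude = 1)
  makePointTargetStack(PointTargetScene(tg, noiseSigma = noiseSigma,
                                        seed = seed),
                       g, nScans = 201, nSamples = 1100)
}

# elevational envelope profile of a stack-like matrix at a sample column
elevProfile <- function(mat, sampleIdx) {
  envelope(mat)[, round(sampleIdx)]
}

# a stack whose aperture is z_s = 0 everywhere (degenerate refocusing)
degenerateStack <- function() {
  g <- ScanGeometry(lf = 20, w = 8, dz = 0.5, fs = 40e6, c = 1.5, n0 = 50)
  set.seed(11)
  AScanStack(matrix(rnorm(20 * 100), 20, 100), g)
}

# noise-free single-ROI kinetic scene
simpleKineticScene <- function(noiseSigma = 0, breathingFraction = 0,
                               nFrames = 120L, seed = 5) {
  rois <- list(list(center = c(16, 16), radius = 6,
                    params = EMMParams(A = 60, t0 = 20, alpha = 0.05,
                                       beta = 0.004, q = 1)))
  KineticScene(c(32L, 32L), rois, noiseSigma = noiseSigma,
               breathingFraction = breathingFraction, nFrames = nFrames,
               frameInterval = 2, seed = seed)
}
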