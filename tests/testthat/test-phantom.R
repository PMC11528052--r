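test_that("focused target energy is confined to its apex scan", {
  g <- stdGeometry(n0 = 300)
  sc <- PointTargetScene(data.frame(depth_mm = 20, elev_mm = 5,
                                    amplitude = 1))
  st <- makePointTargetStack(sc, g, nScans = 101, nSamples = 700)
  truth <- attr(st, "truth")
  apex <- truth$apex_scan[1]
  rowEnergy <- rowSums(st@samples^2)
  expect_equal(which(rowEnergy > 0), apex)
  expect_equal(which.max(envelope(st@samples[apex, ])),
               round(truth$arrival_sample[1]), tolerance = 1)
  expect_equal(truth$arrival_sample[1], 300)
})

test_that("defocused arrivals trace the hyperbolic locus", {
  g <- stdGeometry(n0 = 300)
  sc <- PointTargetScene(data.frame(depth_mm = 30, elev_mm = 10,
                                    amplitude = 1))
  st <- makePointTargetStack(sc, g, nScans = 201, nSamples = 1100)
  env <- envelope(st@samples)
  rowEnergy <- rowSums(st@samples^2)
  hit <- which(rowEnergy > 0.01 * max(rowEnergy))
  ri <- abs(30 - 20)                       # range from focus at the apex, mm
  samplesPerMm <- 40e6 * 1e-6 / 1.5
  for (i in hit) {
    jdz <- (i - attr(st, "truth")$apex_scan[1]) * 0.1
    rij <- sqrt(ri^2 + jdz^2)
    predicted <- 300 + rij * samplesPerMm
    expect_lt(abs(which.max(env[i, ]) - predicted), 1 + 1e-6)
  }
})

test_that("stack energy equals pulse energy times insonified scans", {
  g <- stdGeometry(n0 = 300)
  sc <- PointTargetScene(data.frame(depth_mm = 27, elev_mm = 10,
                                    amplitude = 1))
  st <- makePointTargetStack(sc, g, nScans = 201, nSamples = 1100)
  truth <- attr(st, "truth")
  rowEnergy <- rowSums(st@samples^2)
  active <- which(rowEnergy > 0)
  perScan <- rowEnergy[active]
  # every insonified scan carries one pulse of (near) identical energy
  expect_equal(length(active), truth$n_insonified[1])
  expect_lt(max(abs(perScan - mean(perScan))) / mean(perScan), 0.01)
  expect_lt(abs(sum(rowEnergy) - truth$n_insonified[1] * mean(perScan)) /
              sum(rowEnergy), 0.01)
})

test_that("out-of-record targets raise a named error", {
  g <- stdGeometry(n0 = 300)
  sc <- PointTargetScene(data.frame(depth_mm = 60, elev_mm = 5,
                                    amplitude = 1))
  expect_error(makePointTargetStack(sc, g, nScans = 51, nSamples = 400),
               "target 1")
})

test_that("kinetic movie round-trips its ground truth exactly", {
  mv <- makeKineticMovie(simpleKineticScene())
  truth <- attr(mv, "truth")
  tc <- roiTimecourse(mv, truth$masks[[1]], nBaseline = 5)
  re <- relativeEnhancement(tc)
  expect_lt(max(abs(valuesOf(re) - truth$curves[[1]])), 1e-9)
})

test_that("kinetic movie with noise still supports parameter recovery", {
  sc <- simpleKineticScene(noiseSigma = 0.5, nFrames = 150L, seed = 3)
  mv <- makeKineticMovie(sc)
  truth <- attr(mv, "truth")
  tc <- roiTimecourse(mv, truth$masks[[1]], nBaseline = 8)
  fit <- fitEMM(relativeEnhancement(tc))
  pt <- truth$params[[1]]
  expect_lt(abs(modelParams(fit)@alpha - pt@alpha) / pt@alpha, 0.10)
})

test_that("breathing spikes are injected and removable", {
  sc <- simpleKineticScene(noiseSigma = 0, breathingFraction = 0.1,
                           nFrames = 150L, seed = 9)
  mv <- makeKineticMovie(sc)
  truth <- attr(mv, "truth")
  expect_gt(length(truth$spikeFrames), 0)
  tc <- roiTimecourse(mv, truth$masks[[1]], nBaseline = 5)
  re <- relativeEnhancement(tc)
  filt <- filterBreathingOutliers(re)
  clean <- 100 * ((truth$baselineLevel * (1 + truth$curves[[1]] / 100)) /
                    truth$baselineLevel - 1)
  spikeResidBefore <- sum((valuesOf(re) - clean)[truth$spikeFrames]^2)
  spikeResidAfter <- sum((valuesOf(filt) - clean)[truth$spikeFrames]^2)
  expect_lt(spikeResidAfter, 0.1 * spikeResidBefore)  # >= 90% removed
})

test_that("overlapping ROIs with different kinetics are rejected", {
  rois <- list(
    list(center = c(10, 10), radius = 5,
         params = EMMParams(A = 50, t0 = 5, alpha = 0.1, beta = 0.01, q = 1)),
    list(center = c(12, 12), radius = 5,
         params = EMMParams(A = 20, t0 = 9, alpha = 0.3, beta = 0.02, q = 1)))
  sc <- KineticScene(c(32L, 32L), rois, nFrames = 10L)
  expect_error(makeKineticMovie(sc), "overlap")
})

test_that("tissue presets match their definitions", {
  ab <- makeTissueMap("absorbing-slab", c(10, 10))
  expect_equal(unname(ab@muA), 0.1)
  expect_equal(unname(ab@muS), 0)
  expect_equal(length(unique(as.vector(ab@labels))), 1L)

  tl <- makeTissueMap("two-layer", c(10, 10))
  expect_equal(sort(unique(as.vector(tl@labels))), c(1L, 2L))
  expect_true(all(tl@labels[1:5, ] == 1L))
  expect_true(all(tl@labels[6:10, ] == 2L))
  expect_true(tl@muA[1] != tl@muA[2])

  di <- makeTissueMap("disk-inclusion", c(30, 30))
  inc <- attr(di, "inclusion")
  expect_false(is.null(inc))
  expect_equal(di@labels[inc$center[1], inc$center[2]], 2L)
  expect_equal(di@labels[1, 1], 1L)
  expect_gt(di@muA[2], di@muA[1])

  expect_error(makeTissueMap("no-such-preset", c(10, 10)))
})

test_that("ring forward model honors the geometry", {
  # point at the ring center: identical delay radius / c on all elements
  img <- matrix(0, 65, 65); img[33, 33] <- 1
  ch <- ringForward(img, radius = 10, nElements = 32, fs = 40e6, c = 1.5,
                    pixelSize = 0.1)
  bins <- apply(ch, 1, which.max)
  expect_true(all(bins == bins[1]))
  expect_equal(bins[1], round(10 / 1.5 * 40) + 1)

  # off-center point: per-element delays match exact distances
  img2 <- matrix(0, 65, 65); img2[33, 53] <- 1   # x = +2 mm, y = 0
  ch2 <- ringForward(img2, radius = 10, nElements = 32, fs = 40e6, c = 1.5,
                     pixelSize = 0.1)
  th <- 2 * pi * (0:31) / 32
  d <- sqrt((2 - 10 * cos(th))^2 + (10 * sin(th))^2)
  expect_true(all(abs(apply(ch2, 1, which.max) - (round(d / 1.5 * 40) + 1))
                  <= 1))

  # linearity
  chSum <- ringForward(img + img2, radius = 10, nElements = 32, fs = 40e6,
                       c = 1.5, pixelSize = 0.1)
  expect_equal(chSum, ch + ch2)

  big <- matrix(1, 65, 65)
  expect_error(ringForward(big, radius = 4, nElements = 32, fs = 40e6,
                           c = 1.5, pixelSize = 0.1), "beyond the ring")
})

test_that("ring back-projection localizes points", {
  recOf <- function(row, col) {
    img <- matrix(0, 65, 65); img[row, col] <- 1
    ch <- ringForward(img, radius = 10, nElements = 64, fs = 40e6, c = 1.5,
                      pixelSize = 0.1)
    ringBackproject(ch, radius = 10, fs = 40e6, c = 1.5, pixelSize = 0.1,
                    gridSize = 65)
  }
  rec <- recOf(33, 33)
  pk <- which(rec == max(rec), arr.ind = TRUE)
  expect_lte(max(abs(pk[1, ] - c(33, 33))), 2)

  # two well-separated points give two local maxima at their locations
  imgA <- matrix(0, 65, 65); imgA[20, 20] <- 1; imgA[45, 50] <- 1
  ch <- ringForward(imgA, radius = 10, nElements = 64, fs = 40e6, c = 1.5,
                    pixelSize = 0.1)
  rec2 <- ringBackproject(ch, radius = 10, fs = 40e6, c = 1.5,
                          pixelSize = 0.1, gridSize = 65)
  near <- function(r, c) max(rec2[(r - 2):(r + 2), (c - 2):(c + 2)])
  far <- max(rec2[28:38, 28:38])
  expect_gt(near(20, 20), far)
  expect_gt(near(45, 50), far)
})

test_that("generators are reproducible under a fixed seed", {
  sc <- PointTargetScene(data.frame(depth_mm = 25, elev_mm = 5,
                                    amplitude = 1), noiseSigma = 0.05,
                         seed = 123)
  g <- stdGeometry()
  a <- makePointTargetStack(sc, g, 51, 800)
  b <- makePointTargetStack(sc, g, 51, 800)
  expect_identical(a@samples, b@samples)

  ks <- simpleKineticScene(noiseSigma = 1, breathingFraction = 0.1,
                           nFrames = 40L, seed = 99)
  expect_identical(makeKineticMovie(ks)@frames, makeKineticMovie(ks)@frames)
})
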