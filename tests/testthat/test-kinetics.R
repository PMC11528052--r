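test_that("relative enhancement follows the baseline-normalized formula", {
  base <- ROITimeCourse(0:4, rep(100, 5), baselineValue = 100)
  expect_equal(valuesOf(relativeEnhancement(base)), rep(0, 5))

  up <- ROITimeCourse(0:1, c(100, 150), baselineValue = 100)
  expect_equal(valuesOf(relativeEnhancement(up)), c(0, 50))

  down <- ROITimeCourse(0:1, c(200, 150), baselineValue = 200)
  expect_equal(valuesOf(relativeEnhancement(down)), c(0, -25))

  expect_equal(relativeEnhancement(up)@kind, "relative-enhancement")
  expect_identical(timesOf(relativeEnhancement(up)), timesOf(up))

  bad <- ROITimeCourse(0:1, c(1, 2), baselineValue = NA_real_)
  expect_error(relativeEnhancement(bad), "baseline")
  expect_error(ROITimeCourse(0:1, c(1, 2), baselineValue = -3), "baselineValue")
})

test_that("breathing-outlier filter replaces spikes and nothing else", {
  const <- ROITimeCourse(1:20, rep(10, 20), kind = "relative-enhancement")
  expect_equal(valuesOf(filterBreathingOutliers(const)), rep(10, 20))

  # single spike of 100x the level in an otherwise constant 20-point series
  x <- rep(10, 20); x[8] <- 1000
  spiked <- ROITimeCourse(1:20, x, kind = "relative-enhancement")
  filt <- filterBreathingOutliers(spiked, window = 11, nMad = 3)
  expect_equal(valuesOf(filt)[8], 10)
  expect_equal(valuesOf(filt)[-8], x[-8])

  # identity on a smooth noise-free model curve
  p <- EMMParams(A = 80, t0 = 5, alpha = 0.05, beta = 0.002, q = 1.5)
  tt <- seq(0, 600, by = 2)
  smooth <- ROITimeCourse(tt, emmEvaluate(p, tt), kind = "relative-enhancement")
  out <- filterBreathingOutliers(smooth)
  expect_lt(max(abs(valuesOf(out) - valuesOf(smooth))),
            1e-9 * max(valuesOf(smooth)))

  short <- ROITimeCourse(1:5, rep(1, 5), kind = "relative-enhancement")
  expect_error(filterBreathingOutliers(short), "insufficient")
  expect_error(filterBreathingOutliers(const, window = 4), "odd")
})

test_that("breathing filter matches the reference Hampel on interior samples", {
  set.seed(14)
  x <- cumsum(rnorm(60)) + 20
  x[c(12, 30, 44)] <- x[c(12, 30, 44)] + 40
  tc <- ROITimeCourse(seq_along(x), x, kind = "relative-enhancement")
  mine <- valuesOf(filterBreathingOutliers(tc, window = 11, nMad = 3))
  ref <- pracma::hampel(x, k = 5, t0 = 3)$y
  interior <- 6:55   # reference leaves the first/last k samples unfiltered
  expect_equal(mine[interior], ref[interior])
})

test_that("model evaluation matches the closed form and its limits", {
  p <- EMMParams(A = 100, t0 = 10, alpha = 0.2, beta = 0.01, q = 1)
  # zero before the rise time point, continuous at t0
  expect_equal(emmEvaluate(p, c(0, 5, 9.999999)), rep(0, 3))
  expect_lt(emmEvaluate(p, 10 + 1e-9), 1e-6)
  # independent high-precision evaluation of the closed form at t = 20
  expect_equal(emmEvaluate(p, 20), 100 * (1 - exp(-2)) * exp(-0.1),
               tolerance = 1e-12)
  # beta = 0, q = 1: monotone nondecreasing, supremum A
  p0 <- EMMParams(A = 100, t0 = 10, alpha = 0.2, beta = 0, q = 1)
  v <- emmEvaluate(p0, seq(0, 200, by = 0.5))
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 100))
  expect_equal(emmEvaluate(p0, 1e4), 100, tolerance = 1e-8)
  # doubling fRatio exactly halves the output pointwise
  p2 <- EMMParams(A = 100, t0 = 10, alpha = 0.2, beta = 0.01, q = 1,
                  fRatio = 2)
  tt <- seq(0, 100, by = 0.7)
  expect_equal(emmEvaluate(p2, tt), emmEvaluate(p, tt) / 2)
  # bounded above by A / fRatio everywhere
  expect_true(all(emmEvaluate(p, seq(0, 1000, 0.1)) <= 100))
})

test_that("fit recovers known parameters", {
  pt <- EMMParams(A = 80, t0 = 5, alpha = 0.05, beta = 0.002, q = 1.5)
  tt <- seq(0, 600, by = 1)
  clean <- ROITimeCourse(tt, emmEvaluate(pt, tt),
                         kind = "relative-enhancement")
  fit <- fitEMM(clean)
  expect_true(fit@converged)
  got <- as.numeric(modelParams(fit))
  truth <- as.numeric(pt)
  expect_lt(max(abs(got[1:5] - truth[1:5]) / abs(truth[1:5])), 1e-3)

  # seeded Gaussian noise sigma = 2 RE units: rates within 10%
  set.seed(42)
  noisy <- ROITimeCourse(tt, emmEvaluate(pt, tt) + rnorm(length(tt), sd = 2),
                         kind = "relative-enhancement")
  fn <- fitEMM(noisy)
  pn <- modelParams(fn)
  expect_lt(abs(pn@alpha - pt@alpha) / pt@alpha, 0.10)
  expect_lt(abs(pn@beta - pt@beta) / pt@beta, 0.10)
})

test_that("fit respects the fluence-ratio scaling symmetry", {
  pt <- EMMParams(A = 80, t0 = 5, alpha = 0.05, beta = 0.002, q = 1.5)
  tt <- seq(0, 600, by = 1)
  y <- emmEvaluate(pt, tt)
  f1 <- fitEMM(ROITimeCourse(tt, y, kind = "relative-enhancement"),
               fRatio = 1)
  f2 <- fitEMM(ROITimeCourse(tt, y / 2, kind = "relative-enhancement"),
               fRatio = 2)
  expect_equal(as.numeric(modelParams(f2))[1:5],
               as.numeric(modelParams(f1))[1:5], tolerance = 1e-4)
})

test_that("fit is invariant to uniform time shifts (t0 absorbs them)", {
  pt <- EMMParams(A = 80, t0 = 5, alpha = 0.05, beta = 0.002, q = 1.5)
  tt <- seq(0, 600, by = 1)
  y <- emmEvaluate(pt, tt)
  shift <- 40
  fs <- fitEMM(ROITimeCourse(tt + shift, y, kind = "relative-enhancement"))
  ps <- modelParams(fs)
  expect_equal(ps@t0, pt@t0 + shift, tolerance = 1e-2)
  expect_equal(ps@alpha, pt@alpha, tolerance = 1e-3)
  expect_equal(ps@beta, pt@beta, tolerance = 1e-3)
})

test_that("degenerate fit inputs are rejected", {
  tt <- seq(0, 100, by = 1)
  expect_error(fitEMM(ROITimeCourse(tt, rep(0, length(tt)),
                                    kind = "relative-enhancement")),
               "degenerate")
  expect_error(fitEMM(ROITimeCourse(1:5, 1:5,
                                    kind = "relative-enhancement")),
               "8 samples")
  raw <- ROITimeCourse(tt, tt + 1, baselineValue = 1)
  expect_error(fitEMM(raw), "relative-enhancement")
})

test_that("clearance summary reproduces the closed-form peak time", {
  p <- EMMParams(A = 100, t0 = 10, alpha = 0.2, beta = 0.01, q = 1)
  f <- new("EMMFit", params = p, rss = 0, nPoints = 100L, converged = TRUE)
  s <- clearanceSummary(f, tEnd = 600)
  # grid-search argmax at 1e-3 s resolution as the independent oracle
  grid <- seq(10, 60, by = 1e-3)
  tMaxGrid <- grid[which.max(emmEvaluate(p, grid))]
  expect_equal(s@tMax, 10 + 5 * log(21), tolerance = 1e-12)
  expect_lt(abs(s@tMax - tMaxGrid), 1e-3 + 1e-9)
  # half-life: curve at tMax + tHalf is half the peak
  expect_equal(emmEvaluate(p, s@tMax + s@tHalf), s@reMaxCurve / 2,
               tolerance = 1e-6)
  expect_gt(s@tHalf, 0)
  # unit conversions and amplitude conventions
  expect_equal(s@uAlpha, 60 * 0.2)
  expect_equal(s@eBeta, 60 * 0.01)
  expect_equal(s@reMaxAmplitude, 100)
  expect_lt(s@reMaxCurve, s@reMaxAmplitude)
})

test_that("no elimination phase yields an infinite half-life sentinel", {
  p <- EMMParams(A = 50, t0 = 5, alpha = 0.1, beta = 0, q = 1)
  f <- new("EMMFit", params = p, rss = 0, nPoints = 50L, converged = TRUE)
  s <- clearanceSummary(f, tEnd = 300)
  expect_identical(s@tHalf, Inf)
  expect_equal(s@tMax, 300)  # saturating curve peaks at the window end
})

test_that("AUC behaves like an integral", {
  p <- EMMParams(A = 100, t0 = 10, alpha = 0.2, beta = 0.01, q = 1)
  f <- new("EMMFit", params = p, rss = 0, nPoints = 100L, converged = TRUE)
  aucs <- vapply(c(100, 200, 400, 600),
                 function(te) clearanceSummary(f, te)@auc, numeric(1))
  expect_true(all(diff(aucs) > 0))  # monotone nondecreasing in tEnd
  # rectangle check on the raw-trapezoid companion: constant level C
  C <- 7.5
  const <- ROITimeCourse(seq(0, 100, 1), rep(C, 101),
                         kind = "relative-enhancement")
  expect_equal(rawAUC(const, 100), C * 100)
})

test_that("closed-form peak time matches brute force over random parameters", {
  set.seed(101)
  for (k in 1:20) {
    p <- EMMParams(A = runif(1, 10, 100), t0 = runif(1, 0, 30),
                   alpha = runif(1, 0.05, 1), beta = runif(1, 1e-3, 0.1),
                   q = runif(1, 0.3, 3))
    tMaxCf <- p@t0 + log((p@q * p@alpha + p@beta) / p@beta) / p@alpha
    grid <- seq(p@t0, tMaxCf * 2 + 5, by = 1e-3)
    tMaxGrid <- grid[which.max(emmEvaluate(p, grid))]
    expect_lt(abs(tMaxCf - tMaxGrid), 1e-3 + 1e-9)
  }
})
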