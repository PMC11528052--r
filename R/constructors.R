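#' Construct a region-of-interest time course
#'
#' @param times acquisition times (s), strictly increasing.
#' @param values sampled values (PA intensity a.u. or relative enhancement %).
#' @param baselineValue mean pre-injection PA intensity; required (and > 0)
#'   for raw-intensity courses.
#' @param kind `"raw-intensity"` or `"relative-enhancement"`.
#' @return a [ROITimeCourse-class] object.
#' @examples
#' tc <- ROITimeCourse(0:9, rep(100, 10), baselineValue = 100)
#' @export
ROITimeCourse <- function(times, values, baselineValue = NA_real_,
                          kind = c("raw-intensity", "relative-enhancement")) {
  kind <- match.arg(kind)
  new("ROITimeCourse", times = as.numeric(times), values = as.numeric(values),
      baselineValue = as.numeric(baselineValue), kind = kind)
}

#' Construct empirical-model parameters
#'
#' @param A amplitude (%), > 0.
#' @param t0 rise time point (s), >= 0.
#' @param alpha uptake rate (1/s), > 0.
#' @param beta excretion rate (1/s), >= 0.
#' @param q early-uptake shape exponent, > 0.
#' @param fRatio post/pre-injection fluence ratio, > 0.
#' @return an [EMMParams-class] object.
#' @examples
#' EMMParams(A = 100, t0 = 10, alpha = 0.2, beta = 0.01, q = 1)
#' @export
EMMParams <- function(A, t0, alpha, beta, q = 1, fRatio = 1) {
  new("EMMParams", A = as.numeric(A), t0 = as.numeric(t0),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      q = as.numeric(q), fRatio = as.numeric(fRatio))
}

#' Construct an elevational scan geometry
#'
#' @param lf focus-to-transducer distance (mm).
#' @param w transducer element height (mm).
#' @param dz elevational scan step (mm).
#' @param fs sampling rate (Hz).
#' @param c speed of sound (mm/us). Default 1.5 (water).
#' @param n0 1-based sample index of the acoustic focus.
#' @return a [ScanGeometry-class] object.
#' @examples
#' ScanGeometry(lf = 20, w = 8, dz = 0.1, fs = 40e6, n0 = 400)
#' @export
ScanGeometry <- function(lf, w, dz, fs, c = 1.5, n0) {
  new("ScanGeometry", lf = as.numeric(lf), w = as.numeric(w),
      dz = as.numeric(dz), fs = as.numeric(fs), c = as.numeric(c),
      n0 = as.numeric(n0))
}

#' Construct an A-scan stack
#'
#' @param samples numeric matrix [elevation x time sample].
#' @param geometry a [ScanGeometry-class].
#' @return an [AScanStack-class] object.
#' @export
AScanStack <- function(samples, geometry) {
  new("AScanStack", samples = samples, geometry = geometry)
}

#' Construct a segmented optical tissue map
#'
#' @param labels integer matrix of region labels (1-based).
#' @param muA,muS,g per-label optical properties (1/mm, 1/mm, dimensionless).
#' @param spacing grid spacing (mm).
#' @return a [TissueModel-class] object.
#' @export
TissueModel <- function(labels, muA, muS, g, spacing) {
  storage.mode(labels) <- "integer"
  new("TissueModel", labels = labels, muA = as.numeric(muA),
      muS = as.numeric(muS), g = as.numeric(g), spacing = as.numeric(spacing))
}

#' Construct a dynamic frame series
#'
#' @param frames 3-D numeric array [frame x y x x].
#' @param frameInterval time between frames (s).
#' @param pixelSize pixel edge length (mm).
#' @return a [FrameSeries-class] object.
#' @export
FrameSeries <- function(frames, frameInterval, pixelSize = 0.025) {
  new("FrameSeries", frames = frames, frameInterval = as.numeric(frameInterval),
      pixelSize = as.numeric(pixelSize))
}

#' Construct an ROI mask
#'
#' @param mask logical matrix; at least one pixel TRUE.
#' @param label region name.
#' @return an [ROIMask-class] object.
#' @export
ROIMask <- function(mask, label = "roi") {
  new("ROIMask", mask = mask, label = label)
}
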