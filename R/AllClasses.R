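#' @import methods
#' @importFrom stats fft integrate mvfft median optimize quantile rnorm runif
#'   sd uniroot setNames coef lm
#' @importFrom utils read.csv write.csv head tail
#' @importFrom withr with_seed
#' @useDynLib patrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Region-of-interest time course
#'
#' Holds the sampled photoacoustic (PA) intensity of one region over time,
#' either as raw intensity (arbitrary units) or as relative enhancement
#' (percent change from the pre-injection baseline).
#'
#' @slot times numeric, acquisition times in seconds, strictly increasing.
#' @slot values numeric, PA intensity (a.u.) or relative enhancement (%).
#' @slot baselineValue numeric(1), mean pre-injection PA intensity PA(0);
#'   must be positive while \code{kind == "raw-intensity"}.
#' @slot kind character(1), \code{"raw-intensity"} or
#'   \code{"relative-enhancement"}.
#'
#' @seealso [ROITimeCourse()] constructor, [relativeEnhancement()]
#' @exportClass ROITimeCourse
setClass("ROITimeCourse",
  representation(
    times = "numeric",
    values = "numeric",
    baselineValue = "numeric",
    kind = "character"
  ),
  prototype(baselineValue = NA_real_, kind = "raw-intensity")
)

setValidity("ROITimeCourse", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!object@kind %in% c("raw-intensity", "relative-enhancement"))
    msg <- c(msg, "kind must be 'raw-intensity' or 'relative-enhancement'")
  if (identical(object@kind, "raw-intensity") &&
      !is.na(object@baselineValue) && object@baselineValue <= 0)
    msg <- c(msg, "baselineValue must be > 0 for raw-intensity courses")
  if (length(msg)) msg else TRUE
})

#' Parameters of the fluence-corrected empirical enhancement model
#'
#' The model describes relative enhancement after a rise time point `t0` as
#' an exponential-saturation uptake raised to a shape exponent `q`, damped by
#' exponential elimination, scaled by `A / fRatio` where `fRatio` is the
#' post- over pre-injection light-fluence ratio at the region:
#' \deqn{RE(t) = (A/F_{ratio}) [1 - e^{-\alpha (t-t_0)}]^{q} e^{-\beta (t-t_0)}, \quad t \ge t_0}
#' and 0 before `t0`.
#'
#' @slot A amplitude, percent RE units, > 0.
#' @slot t0 rise time point, seconds, >= 0.
#' @slot alpha uptake rate, 1/s, > 0.
#' @slot beta excretion rate, 1/s, >= 0.
#' @slot q early-uptake shape exponent, dimensionless, > 0.
#' @slot fRatio post/pre-injection fluence ratio, dimensionless, > 0.
#'
#' @seealso [EMMParams()], [emmEvaluate()], [fitEMM()]
#' @exportClass EMMParams
setClass("EMMParams",
  representation(A = "numeric", t0 = "numeric", alpha = "numeric",
                 beta = "numeric", q = "numeric", fRatio = "numeric"),
  prototype(fRatio = 1)
)

setValidity("EMMParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@A) || object@A <= 0) msg <- c(msg, "A must be a positive scalar")
  if (!one(object@t0) || object@t0 < 0) msg <- c(msg, "t0 must be a nonnegative scalar")
  if (!one(object@alpha) || object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (!one(object@beta) || object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (!one(object@q) || object@q <= 0) msg <- c(msg, "q must be > 0")
  if (!one(object@fRatio) || object@fRatio <= 0) msg <- c(msg, "fRatio must be > 0")
  if (length(msg)) msg else TRUE
})

#' Fitted empirical-model result
#'
#' @slot params [EMMParams-class] point estimates.
#' @slot rss residual sum of squares, >= 0.
#' @slot nPoints number of fitted samples.
#' @slot converged logical(1).
#' @slot covariance parameter covariance matrix (may be 0 x 0 when
#'   unavailable).
#'
#' @exportClass EMMFit
setClass("EMMFit",
  representation(params = "EMMParams", rss = "numeric", nPoints = "integer",
                 converged = "logical", covariance = "matrix"),
  prototype(covariance = matrix(numeric(), 0, 0))
)

setValidity("EMMFit", function(object) {
  msg <- character()
  if (object@rss < 0) msg <- c(msg, "rss must be >= 0")
  if (object@nPoints < 5L) msg <- c(msg, "nPoints must be >= number of free parameters")
  if (length(msg)) msg else TRUE
})

#' Clearance-parameter summary derived from a fitted curve
#'
#' @slot reMaxAmplitude A/fRatio, the model's upper amplitude (%).
#' @slot reMaxCurve peak value of the fitted curve (%), <= reMaxAmplitude.
#' @slot tMax time of the curve maximum (s).
#' @slot tHalf elapsed time after tMax at which the curve falls to half its
#'   peak (s); `Inf` when beta == 0 (no elimination phase).
#' @slot uAlpha average uptake rate, 1/min (60 * alpha).
#' @slot eBeta average excretion rate, 1/min (60 * beta).
#' @slot auc area under the fitted curve over [0, tEnd] (%*s).
#' @slot tEnd right end of the integration window (s).
#'
#' @exportClass ClearanceSummary
setClass("ClearanceSummary",
  representation(reMaxAmplitude = "numeric", reMaxCurve = "numeric",
                 tMax = "numeric", tHalf = "numeric", uAlpha = "numeric",
                 eBeta = "numeric", auc = "numeric", tEnd = "numeric"))

setValidity("ClearanceSummary", function(object) {
  msg <- character()
  if (is.finite(object@tHalf) && object@tHalf <= 0)
    msg <- c(msg, "tHalf must be > 0 when finite")
  if (object@reMaxCurve > object@reMaxAmplitude * (1 + 1e-9))
    msg <- c(msg, "reMaxCurve cannot exceed reMaxAmplitude")
  if (object@auc < 0) msg <- c(msg, "auc must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Elevational scan geometry of a focused (virtual-detector) transducer
#'
#' @slot lf focus-to-transducer distance (mm).
#' @slot w transducer element height (mm).
#' @slot dz elevational step between neighboring scans (mm).
#' @slot fs sampling rate (Hz).
#' @slot c speed of sound in coupling medium (mm/us).
#' @slot n0 sample index (1-based) at which the acoustic focus arrives.
#'
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(lf = "numeric", w = "numeric", dz = "numeric",
                 fs = "numeric", c = "numeric", n0 = "numeric"))

setValidity("ScanGeometry", function(object) {
  vals <- c(lf = object@lf, w = object@w, dz = object@dz,
            fs = object@fs, c = object@c, n0 = object@n0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all geometry fields must be positive finite scalars")
  TRUE
})

#' Stack of elevational A-scans
#'
#' @slot samples numeric matrix [elevation index x time sample] of PA
#'   amplitude.
#' @slot geometry [ScanGeometry-class].
#'
#' @exportClass AScanStack
setClass("AScanStack",
  representation(samples = "matrix", geometry = "ScanGeometry"))

setValidity("AScanStack", function(object) {
  if (!is.numeric(object@samples)) return("samples must be numeric")
  if (any(!is.finite(object@samples))) return("samples must be finite")
  if (object@geometry@n0 > ncol(object@samples))
    return("geometry n0 exceeds the number of time samples")
  TRUE
})

#' Synthetic-aperture refocusing result
#'
#' @slot paSaft delay-and-sum refocused stack, same shape as the input.
#' @slot cf coherence factor per pixel; in [0, 1] under the default
#'   count normalization (the alternative `zs` normalization, kept to
#'   mirror the conventional printed formula, can exceed 1 on fully
#'   coherent apertures).
#' @slot paCfSaft elementwise product paSaft * cf.
#'
#' @exportClass SAFTResult
setClass("SAFTResult",
  representation(paSaft = "matrix", cf = "matrix", paCfSaft = "matrix"))

setValidity("SAFTResult", function(object) {
  msg <- character()
  if (!all(dim(object@paSaft) == dim(object@cf)) ||
      !all(dim(object@paSaft) == dim(object@paCfSaft)))
    msg <- c(msg, "paSaft, cf and paCfSaft must share dimensions")
  if (any(object@cf < -1e-12))
    msg <- c(msg, "cf must be nonnegative")
  if (max(abs(object@paCfSaft - object@paSaft * object@cf)) > 1e-8 * (1 + max(abs(object@paSaft))))
    msg <- c(msg, "paCfSaft must equal paSaft * cf elementwise")
  if (length(msg)) msg else TRUE
})

#' Segmented 2-D optical tissue map
#'
#' A labeled grid where each label carries absorption coefficient mu_a
#' (1/mm), scattering coefficient mu_s (1/mm) and scattering anisotropy g.
#' Rows index depth z (row 1 = illuminated top surface), columns index the
#' lateral coordinate x.
#'
#' @slot labels integer matrix of region labels (values index the property
#'   vectors).
#' @slot muA named numeric, absorption per label (1/mm, >= 0).
#' @slot muS named numeric, scattering per label (1/mm, >= 0).
#' @slot g named numeric, anisotropy per label in (-1, 1).
#' @slot spacing grid spacing (mm), > 0.
#'
#' @exportClass TissueModel
setClass("TissueModel",
  representation(labels = "matrix", muA = "numeric", muS = "numeric",
                 g = "numeric", spacing = "numeric"))

setValidity("TissueModel", function(object) {
  msg <- character()
  labs <- sort(unique(as.vector(object@labels)))
  if (length(object@muA) < max(labs) || length(object@muS) < max(labs) ||
      length(object@g) < max(labs))
    msg <- c(msg, "every label must have mu_a, mu_s and g defined")
  if (any(object@muA < 0) || any(object@muS < 0))
    msg <- c(msg, "mu_a and mu_s must be >= 0")
  if (any(abs(object@g) >= 1)) msg <- c(msg, "g must lie in (-1, 1)")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Simulated light-fluence map
#'
#' @slot values numeric matrix of fluence (photon weight per unit area,
#'   consistent arbitrary units), same shape as the tissue grid, >= 0.
#' @slot nPhotons photon count used.
#' @slot seed RNG seed used.
#'
#' @exportClass FluenceMap
setClass("FluenceMap",
  representation(values = "matrix", nPhotons = "numeric", seed = "numeric"))

setValidity("FluenceMap", function(object) {
  if (any(object@values < 0)) return("fluence values must be >= 0")
  TRUE
})

#' Dynamic 2-D frame series
#'
#' @slot frames 3-D numeric array [frame x y x x].
#' @slot frameInterval time between frames (s), > 0.
#' @slot pixelSize pixel edge length (mm), > 0.
#'
#' @exportClass FrameSeries
setClass("FrameSeries",
  representation(frames = "array", frameInterval = "numeric",
                 pixelSize = "numeric"))

setValidity("FrameSeries", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L || dim(object@frames)[1] < 1L)
    msg <- c(msg, "frames must be a 3-D array with >= 1 frame")
  if (any(!is.finite(object@frames))) msg <- c(msg, "frames must be finite")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Boolean region-of-interest mask
#'
#' @slot mask logical matrix matching the frame shape; at least one TRUE.
#' @slot label character(1) region name.
#'
#' @exportClass ROIMask
setClass("ROIMask",
  representation(mask = "matrix", label = "character"),
  prototype(label = "roi"))

setValidity("ROIMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("mask must be nonempty")
  TRUE
})
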