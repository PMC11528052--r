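#' @rdname ROITimeCourse-class
#' @export
setMethod("timesOf", "ROITimeCourse", function(x) x@times)

#' @rdname ROITimeCourse-class
#' @export
setMethod("valuesOf", "ROITimeCourse", function(x) x@values)

#' @rdname ROITimeCourse-class
#' @export
setMethod("length", "ROITimeCourse", function(x) length(x@times))

#' @rdname EMMFit-class
#' @export
setMethod("modelParams", "EMMFit", function(x) x@params)

#' @describeIn EMMParams-class coerce parameters to a named numeric vector
#'   (A, t0, alpha, beta, q, fRatio).
#' @param x an `EMMParams` object.
#' @export
setMethod("as.numeric", "EMMParams", function(x) {
  c(A = x@A, t0 = x@t0, alpha = x@alpha, beta = x@beta, q = x@q,
    fRatio = x@fRatio)
})

#' @describeIn ClearanceSummary-class coerce to a named list of clearance
#'   parameters.
#' @param x a `ClearanceSummary` object.
#' @param ... ignored.
#' @export
setMethod("as.list", "ClearanceSummary", function(x, ...) {
  list(re_max_amplitude_pct = x@reMaxAmplitude,
       re_max_curve_pct = x@reMaxCurve,
       t_max_s = x@tMax, t_half_s = x@tHalf,
       u_alpha_per_min = x@uAlpha, e_beta_per_min = x@eBeta,
       auc = x@auc, t_end_s = x@tEnd)
})

setMethod("show", "ROITimeCourse", function(object) {
  cat(sprintf("ROITimeCourse (%s): %d samples, t = [%g, %g] s\n",
              object@kind, length(object@times),
              min(object@times), max(object@times)))
  if (identical(object@kind, "raw-intensity"))
    cat(sprintf("  baseline PA(0) = %g\n", object@baselineValue))
})

setMethod("show", "EMMParams", function(object) {
  cat("EMMParams:\n")
  cat(sprintf("  A = %.4g %%, t0 = %.4g s, alpha = %.4g /s, beta = %.4g /s, q = %.4g, fRatio = %.4g\n",
              object@A, object@t0, object@alpha, object@beta, object@q,
              object@fRatio))
})

setMethod("show", "EMMFit", function(object) {
  cat(sprintf("EMMFit (%s, n = %d, rss = %.4g)\n",
              if (object@converged) "converged" else "NOT converged",
              object@nPoints, object@rss))
  show(object@params)
})

setMethod("show", "ClearanceSummary", function(object) {
  cat("ClearanceSummary:\n")
  cat(sprintf("  RE_max (amplitude A/fRatio) = %.4g %%\n", object@reMaxAmplitude))
  cat(sprintf("  RE_max (curve peak)         = %.4g %%\n", object@reMaxCurve))
  cat(sprintf("  T_max = %.4g s, T_1/2 = %s s\n", object@tMax,
              if (is.finite(object@tHalf)) sprintf("%.4g", object@tHalf) else "Inf"))
  cat(sprintf("  U_alpha = %.4g /min, E_beta = %.4g /min\n",
              object@uAlpha, object@eBeta))
  cat(sprintf("  AUC[0, %g s] = %.4g\n", object@tEnd, object@auc))
})

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: lf = %g mm, w = %g mm, dz = %g mm, fs = %g Hz, c = %g mm/us, n0 = %g\n",
              object@lf, object@w, object@dz, object@fs, object@c, object@n0))
})

setMethod("show", "AScanStack", function(object) {
  cat(sprintf("AScanStack: %d elevational scans x %d samples\n",
              nrow(object@samples), ncol(object@samples)))
  show(object@geometry)
})

setMethod("show", "SAFTResult", function(object) {
  cat(sprintf("SAFTResult: %d x %d, CF in [%.3f, %.3f]\n",
              nrow(object@cf), ncol(object@cf), min(object@cf), max(object@cf)))
})

setMethod("show", "TissueModel", function(object) {
  cat(sprintf("TissueModel: %d x %d grid, spacing %g mm, %d region(s)\n",
              nrow(object@labels), ncol(object@labels), object@spacing,
              length(unique(as.vector(object@labels)))))
})

setMethod("show", "FluenceMap", function(object) {
  cat(sprintf("FluenceMap: %d x %d, %g photons, seed %g\n",
              nrow(object@values), ncol(object@values), object@nPhotons,
              object@seed))
})

setMethod("show", "FrameSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSeries: %d frames of %d x %d, interval %g s, pixel %g mm\n",
              d[1], d[2], d[3], object@frameInterval, object@pixelSize))
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask '%s': %d px of %d x %d\n", object@label,
              sum(object@mask), nrow(object@mask), ncol(object@mask)))
})
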