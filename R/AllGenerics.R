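#' @rdname ROITimeCourse-class
#' @param object,x an object.
#' @export
setGeneric("timesOf", function(x) standardGeneric("timesOf"))

#' @rdname ROITimeCourse-class
#' @export
setGeneric("valuesOf", function(x) standardGeneric("valuesOf"))

#' @rdname EMMFit-class
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' Convert a raw-intensity time course to relative enhancement
#'
#' Relative enhancement is the percent change of PA intensity from the
#' pre-injection baseline: `RE(t) = 100 * (PA(t) - PA(0)) / PA(0)`.
#'
#' @param raw a raw-intensity [ROITimeCourse-class] with positive
#'   `baselineValue`.
#' @return a relative-enhancement [ROITimeCourse-class] on the same times.
#' @examples
#' tc <- ROITimeCourse(0:4, c(100, 100, 150, 120, 110), baselineValue = 100)
#' valuesOf(relativeEnhancement(tc))
#' @export
setGeneric("relativeEnhancement",
           function(raw) standardGeneric("relativeEnhancement"))

#' Synthetic-aperture refocusing with coherence-factor weighting
#'
#' @param stack an [AScanStack-class].
#' @param ... passed to methods; see [applySAFT,AScanStack-method].
#' @export
setGeneric("applySAFT", function(stack, ...) standardGeneric("applySAFT"))
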