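#' Simulate light fluence in a segmented tissue map by Monte Carlo
#'
#' Weighted 2-D photon transport: scattering free paths are drawn from the
#' local scattering coefficient, absorption attenuates the photon weight
#' continuously along each ray segment, and per-cell fluence is scored with
#' a track-length estimator that reduces to the deposited-weight estimator
#' where `mu_a > 0` and to the path-length estimator where `mu_a = 0`.
#' Scattering deflections follow the 2-D Henyey-Greenstein phase function;
#' photons below weight 1e-4 undergo Russian roulette with survival
#' probability 0.1. Grid boundaries are matched (no refractive-index
#' mismatch); photons leaving the grid are counted as escaped.
#'
#' @param tissue a [TissueModel-class].
#' @param illumination `"pencil"` (top center, downward), `"uniform-top"`
#'   (uniform over the top edge, downward) or `"ring-inward"` (`ringN`
#'   equally spaced inward-pointing sources on a circle around the grid
#'   center).
#' @param nPhotons photon count, >= 1e4.
#' @param seed RNG seed (required; results are bit-reproducible given the
#'   seed).
#' @param ringN number of ring sources (ring-inward only).
#' @param checkEnergy if TRUE (default), stop unless
#'   launched = deposited + escaped + roulette adjustment within 1e-6
#'   relative.
#' @return a [FluenceMap-class]; the energy ledger is attached as
#'   `attr(, "energy")` (launched, deposited, escaped, roulette_net).
#' @examples
#' tm <- makeTissueMap("absorbing-slab", c(40, 40))
#' fl <- simulateFluence(tm, "pencil", nPhotons = 1e4, seed = 1)
#' @export
simulateFluence <- function(tissue,
                            illumination = c("pencil", "uniform-top",
                                             "ring-inward"),
                            nPhotons, seed, ringN = 16L,
                            checkEnergy = TRUE) {
  stopifnot(is(tissue, "TissueModel"))
  illumination <- match.arg(illumination)
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  if (nPhotons < 1e4) stop("nPhotons must be >= 1e4")
  beam <- match(illumination, c("pencil", "uniform-top", "ring-inward")) - 1L

  res <- withr::with_seed(as.integer(seed),
    .mcFluenceCpp(tissue@labels, tissue@muA, tissue@muS, tissue@g,
                  tissue@spacing, as.numeric(nPhotons), beam,
                  as.integer(ringN)))

  if (checkEnergy) {
    bal <- res$deposited + res$escaped + res$roulette_net
    if (abs(bal - res$launched) > 1e-6 * res$launched)
      stop(sprintf("energy bookkeeping violated: launched %g vs accounted %g",
                   res$launched, bal))
  }
  out <- new("FluenceMap", values = res$fluence / res$launched,
             nPhotons = as.numeric(nPhotons), seed = as.numeric(seed))
  attr(out, "energy") <- res[c("launched", "deposited", "escaped",
                               "roulette_net")]
  out
}

#' Post/pre-injection fluence ratio over a region
#'
#' The ratio of mean post-injection to mean pre-injection fluence inside the
#' region of interest; used as the fixed `fRatio` scaling in the
#' fluence-corrected enhancement model.
#'
#' @param pre,post [FluenceMap-class] objects of equal shape.
#' @param roi an [ROIMask-class] or logical matrix of the same shape.
#' @return a dimensionless scalar.
#' @export
fluenceRatio <- function(pre, post, roi) {
  m <- if (is(roi, "ROIMask")) roi@mask else roi
  stopifnot(is.logical(m))
  if (!all(dim(pre@values) == dim(post@values)) ||
      !all(dim(pre@values) == dim(m)))
    stop("pre, post and roi must share dimensions")
  if (!any(m)) stop("roi must be nonempty")
  preMean <- mean(pre@values[m])
  if (preMean <= 0) stop("undefined ratio: zero pre-injection fluence in roi")
  mean(post@values[m]) / preMean
}

#' Compensate an image for light-fluence attenuation
#'
#' Divides the image by the fluence map, with the divisor floored at
#' `floorFraction` of the maximum fluence so that near-zero-fluence pixels
#' are not blown up.
#'
#' @param frame numeric matrix (PA image).
#' @param fluence a [FluenceMap-class] or numeric matrix of the same shape.
#' @param floorFraction divisor floor as a fraction of max fluence,
#'   in (0, 1); default 0.01.
#' @return the compensated image (same shape).
#' @export
correctFrame <- function(frame, fluence, floorFraction = 0.01) {
  fl <- if (is(fluence, "FluenceMap")) fluence@values else fluence
  if (!all(dim(frame) == dim(fl))) stop("frame and fluence shapes differ")
  if (floorFraction <= 0 || floorFraction >= 1)
    stop("floorFraction must lie in (0, 1)")
  floorVal <- floorFraction * max(fl)
  if (floorVal <= 0) stop("fluence map has no positive values")
  frame / pmax(fl, floorVal)
}

#' Signal-to-background ratio of an image
#'
#' Linear ratio of the mean intensity inside the signal region to the mean
#' intensity inside the background region.
#'
#' @param frame numeric matrix.
#' @param signalRoi,backgroundRoi disjoint nonempty [ROIMask-class] objects
#'   or logical matrices.
#' @return a scalar SBR.
#' @export
signalToBackground <- function(frame, signalRoi, backgroundRoi) {
  s <- if (is(signalRoi, "ROIMask")) signalRoi@mask else signalRoi
  b <- if (is(backgroundRoi, "ROIMask")) backgroundRoi@mask else backgroundRoi
  if (!any(s) || !any(b)) stop("both rois must be nonempty")
  if (any(s & b)) stop("signal and background rois must be disjoint")
  bg <- mean(frame[b])
  if (bg <= 0) stop("undefined SBR: background mean must be > 0")
  mean(frame[s]) / bg
}
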