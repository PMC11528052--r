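#' Pre-injection baseline image
#'
#' Pixelwise mean of the first `nBaseline` frames, acquired before the
#' contrast agent is injected. Acquisitions in this workflow typically
#' average the first 600 frames; scaled-down synthetic movies use fewer.
#'
#' @param series a [FrameSeries-class].
#' @param nBaseline number of leading frames to average (>= 1).
#' @return numeric matrix [y x x].
#' @export
baselineImage <- function(series, nBaseline = 600L) {
  stopifnot(is(series, "FrameSeries"))
  nBaseline <- as.integer(nBaseline)
  if (nBaseline < 1L) stop("nBaseline must be >= 1")
  if (nBaseline > dim(series@frames)[1])
    stop("nBaseline exceeds the number of frames")
  if (nBaseline == 1L) return(series@frames[1, , ])
  apply(series@frames[seq_len(nBaseline), , , drop = FALSE], c(2, 3), mean)
}

# local box mean with replicated borders
.boxMean <- function(img, window) {
  k <- matrix(1 / (window * window), window, window)
  EBImage::filter2(img, k, boundary = "replicate")
}

#' Locally adaptive (Wiener-type) denoising
#'
#' Estimates a local mean and variance in a `window x window` neighborhood
#' and shrinks each pixel toward its local mean by
#' `max(0, 1 - nu / sigma2_local)`, where the noise power `nu` is estimated
#' as the mean of the local variances over the whole image. Flat regions are
#' smoothed fully; high-variance structures (edges, vessels) are preserved.
#'
#' @param image numeric matrix.
#' @param window odd window size >= 3 (default 3).
#' @return the denoised image.
#' @export
adaptiveDenoise <- function(image, window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  m <- .boxMean(image, window)
  v <- pmax(.boxMean(image^2, window) - m^2, 0)
  nu <- mean(v)
  gain <- ifelse(v > nu, 1 - nu / v, 0)
  out <- m + gain * (image - m)
  dimnames(out) <- dimnames(image)
  out
}

#' Differential image against the baseline
#'
#' @param frame,baseline numeric matrices of equal shape.
#' @return signed difference `frame - baseline`.
#' @export
differentialFrame <- function(frame, baseline) {
  if (!all(dim(frame) == dim(baseline)))
    stop("frame and baseline shapes differ")
  frame - baseline
}

#' Suppress interference below a fraction of the maximum
#'
#' Pixels below `fraction * referenceMax` are zeroed; all others are kept
#' unchanged (pixels exactly at the threshold are kept). `referenceMax`
#' defaults to the image's own maximum but should be the global maximum over
#' the whole differential series so that late, faint frames are not
#' renormalized frame by frame.
#'
#' @param image numeric matrix.
#' @param fraction threshold fraction in [0, 1] (default 0.2).
#' @param referenceMax the maximum against which the threshold is taken.
#' @return the thresholded image; all-zero when `referenceMax <= 0`.
#' @export
thresholdSuppress <- function(image, fraction = 0.2,
                              referenceMax = max(image)) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (referenceMax <= 0) return(array(0, dim(image)))
  out <- image
  out[out < fraction * referenceMax] <- 0
  out
}

# Gaussian-derivative kernels for the Hessian at scale sigma (pixels);
# support truncated at 3 sigma or the image half-size, whichever is smaller
.gaussKernel <- function(sigma, order, rMax = Inf) {
  r <- min(max(1L, ceiling(3 * sigma)), rMax)
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         # remove the truncation residual so flat regions map to exactly 0
         "2" = { k <- (x^2 - sigma^2) / sigma^4 * g; k - mean(k) })
}

.hessian <- function(img, sigma) {
  rMax <- (min(dim(img)) - 1L) %/% 2L
  k0 <- .gaussKernel(sigma, 0, rMax)
  k1 <- .gaussKernel(sigma, 1, rMax)
  k2 <- .gaussKernel(sigma, 2, rMax)
  sep <- function(img, kr, kc) {
    tmp <- EBImage::filter2(img, matrix(kr, ncol = 1), boundary = "replicate")
    EBImage::filter2(tmp, matrix(kc, nrow = 1), boundary = "replicate")
  }
  list(xx = sep(img, k0, k2), yy = sep(img, k2, k0), xy = sep(img, k1, k1))
}

#' Frangi vesselness enhancement
#'
#' Standard 2-D Frangi filter: at each scale the Gaussian-smoothed Hessian
#' eigenvalues (|lambda1| <= |lambda2|) define a blob-to-tube ratio
#' `Rb = lambda1 / lambda2` and a structure strength
#' `S = sqrt(lambda1^2 + lambda2^2)`; the response is
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` where
#' `lambda2 < 0` (bright tubes on dark background) and 0 elsewhere, with
#' scale normalization `sigma^2` applied to the Hessian. The output is the
#' maximum over scales and lies in [0, 1] by construction.
#'
#' @param image numeric 2-D matrix.
#' @param scales Gaussian scales in pixels (default 1:4).
#' @param beta blob-ness sensitivity (default 0.5).
#' @param c structure-strength sensitivity; default half the maximum Hessian
#'   norm per scale.
#' @return vesselness map in [0, 1].
#' @export
frangiVesselness <- function(image, scales = 1:4, beta = 0.5, c = NULL) {
  stopifnot(length(dim(image)) == 2L, length(scales) >= 1L)
  best <- array(0, dim(image))
  # floor below which Hessian structure is convolution rounding noise
  sFloor <- 1e-8 * max(abs(image), .Machine$double.eps)
  for (s in scales) {
    H <- .hessian(image, s)
    hxx <- s^2 * H$xx; hyy <- s^2 * H$yy; hxy <- s^2 * H$xy
    tmp <- sqrt(pmax((hxx - hyy)^2 / 4 + hxy^2, 0))
    mu <- (hxx + hyy) / 2
    l1 <- mu + tmp
    l2 <- mu - tmp
    # order by magnitude: |lam1| <= |lam2|
    swap <- abs(l1) > abs(l2)
    lam1 <- ifelse(swap, l2, l1)
    lam2 <- ifelse(swap, l1, l2)
    S <- sqrt(lam1^2 + lam2^2)
    if (max(S) <= sFloor) next
    cc <- if (is.null(c)) max(S) / 2 else c
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cc^2)))
    v[lam2 >= 0] <- 0          # bright-tube polarity only
    best <- pmax(best, v)
  }
  best
}

#' Pseudo-color overlay of signal on anatomy
#'
#' The anatomy image is rendered as grayscale; the (nonnegative) signal is
#' mapped through a pseudo-color map and alpha-blended on top with alpha
#' proportional to the normalized signal, so zero-signal pixels show pure
#' anatomy and saturated pixels show the top color of the map.
#'
#' @param anatomy numeric matrix (any range; min-max scaled to [0, 1]).
#' @param signal nonnegative numeric matrix of the same shape.
#' @param colormap a function mapping values in [0, 1] to n x 3 RGB rows;
#'   default a black-red-yellow "hot" ramp.
#' @param signalMax normalization maximum for the signal (defaults to its
#'   own max; pass the series-wide max for consistent scaling).
#' @return an [y, x, 3] RGB array in [0, 1].
#' @export
overlayPseudoColor <- function(anatomy, signal, colormap = NULL,
                               signalMax = max(signal)) {
  if (!all(dim(anatomy) == dim(signal)))
    stop("anatomy and signal shapes differ")
  if (any(signal < 0)) stop("signal must be nonnegative")
  if (is.null(colormap)) {
    colormap <- function(v) {
      r <- pmin(3 * v, 1)
      g <- pmin(pmax(3 * v - 1, 0), 1)
      b <- pmin(pmax(3 * v - 2, 0), 1)
      cbind(r, g, b)
    }
  }
  rng <- range(anatomy)
  gray <- if (diff(rng) > 0) (anatomy - rng[1]) / diff(rng)
          else array(0, dim(anatomy))
  a <- if (signalMax > 0) pmin(signal / signalMax, 1) else array(0, dim(signal))
  rgbSig <- colormap(as.vector(a))
  out <- array(0, c(dim(anatomy), 3L))
  for (ch in 1:3) {
    out[, , ch] <- (1 - a) * gray + a * array(rgbSig[, ch], dim(anatomy))
  }
  out
}

#' Extract an ROI time course from a frame series
#'
#' Per-frame mean of the raw (unenhanced) pixel values inside the mask.
#' Quantification always runs on raw reconstructed frames; the display
#' pipeline (denoise, threshold, vesselness, overlay) operates on copies
#' and never feeds back into this path.
#'
#' @param series a [FrameSeries-class] of raw frames.
#' @param roi an [ROIMask-class] or logical matrix matching the frame shape.
#' @param nBaseline if > 0, the mean of the first `nBaseline` frame means
#'   is stored as the course's baseline PA(0).
#' @return a raw-intensity [ROITimeCourse-class]; times start at 0 with the
#'   series' frame interval.
#' @export
roiTimecourse <- function(series, roi, nBaseline = 0L) {
  stopifnot(is(series, "FrameSeries"))
  m <- if (is(roi, "ROIMask")) roi@mask else roi
  d <- dim(series@frames)
  if (!all(dim(m) == d[2:3])) stop("roi does not match the frame shape")
  if (!any(m)) stop("roi must be nonempty")
  idx <- which(m)
  vals <- vapply(seq_len(d[1]),
                 function(k) mean(series@frames[k, , ][idx]), numeric(1))
  base <- if (nBaseline > 0L) mean(vals[seq_len(nBaseline)]) else NA_real_
  ROITimeCourse(times = (seq_len(d[1]) - 1) * series@frameInterval,
                values = vals, baselineValue = base, kind = "raw-intensity")
}

#' Run the full dynamic-tracking display pipeline on one frame
#'
#' Convenience composition used for rendering: denoise, subtract the
#' baseline, suppress below the threshold fraction of the series-wide
#' differential maximum, then overlay on the vesselness-enhanced anatomy.
#'
#' @param frame raw frame (matrix).
#' @param baseline baseline image from [baselineImage()].
#' @param seriesMax global maximum of the differential images over the
#'   series.
#' @param fraction threshold fraction (default 0.2).
#' @param scales Frangi scales for the anatomy enhancement.
#' @return list with `differential`, `suppressed`, `anatomy` and `rgb`.
#' @export
trackFrame <- function(frame, baseline, seriesMax, fraction = 0.2,
                       scales = 1:4) {
  den <- adaptiveDenoise(frame)
  diffImg <- differentialFrame(den, baseline)
  sup <- thresholdSuppress(diffImg, fraction, referenceMax = seriesMax)
  anat <- frangiVesselness(baseline, scales = scales)
  rgb <- overlayPseudoColor(anat, pmax(sup, 0), signalMax = max(seriesMax, 0))
  list(differential = diffImg, suppressed = sup, anatomy = anat, rgb = rgb)
}
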