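#' Point-target scene for elevational scan simulation
#'
#' @slot targets data.frame with columns `depth_mm` (> 0), `elev_mm` and
#'   `amplitude` (> 0).
#' @slot f0 pulse center frequency (Hz).
#' @slot bandwidth fractional pulse bandwidth (FWHM / f0).
#' @slot noiseSigma additive Gaussian noise s.d. (amplitude units).
#' @slot seed RNG seed.
#' @exportClass PointTargetScene
setClass("PointTargetScene",
  representation(targets = "data.frame", f0 = "numeric",
                 bandwidth = "numeric", noiseSigma = "numeric",
                 seed = "numeric"))

setValidity("PointTargetScene", function(object) {
  tg <- object@targets
  need <- c("depth_mm", "elev_mm", "amplitude")
  if (!all(need %in% names(tg))) return("targets needs depth_mm, elev_mm, amplitude")
  if (any(tg$depth_mm <= 0)) return("target depths must be > 0")
  if (any(tg$amplitude <= 0)) return("target amplitudes must be > 0")
  TRUE
})

#' @param targets data.frame with `depth_mm`, `elev_mm`, `amplitude`.
#' @param f0 pulse center frequency (Hz), default 5.5 MHz.
#' @param bandwidth fractional bandwidth, default 0.6.
#' @param noiseSigma additive Gaussian noise s.d., default 0.
#' @param seed RNG seed.
#' @rdname PointTargetScene-class
#' @export
PointTargetScene <- function(targets, f0 = 5.5e6, bandwidth = 0.6,
                             noiseSigma = 0, seed = 1L) {
  new("PointTargetScene", targets = targets, f0 = f0, bandwidth = bandwidth,
      noiseSigma = noiseSigma, seed = as.numeric(seed))
}

#' Simulate a defocused elevational A-scan stack
#'
#' Virtual-detector forward model for a focused transducer scanned in
#' elevation. A target at one-way depth `l_t` and elevational position
#' `e_t` is seen by scan `i` (elevation `y_i = (i-1) dz`) with path length
#' `lf + sign(l_t - lf) * sqrt((l_t - lf)^2 + (y_i - e_t)^2)`; a
#' Gaussian-enveloped tone burst is inserted at the corresponding sample.
#' The target only insonifies scans within the hourglass acceptance
#' `|y_i - e_t| <= |l_t - lf| w / (2 lf)` (its apex scan is always
#' included). Seeded Gaussian noise is added last.
#'
#' @param scene a [PointTargetScene-class].
#' @param geometry a [ScanGeometry-class].
#' @param nScans number of elevational positions.
#' @param nSamples record length per scan.
#' @return an [AScanStack-class] with the ground-truth table attached as
#'   `attr(, "truth")` (per target: apex scan, arrival sample at apex,
#'   hourglass half-width in mm and scans).
#' @export
makePointTargetStack <- function(scene, geometry, nScans, nSamples) {
  stopifnot(is(scene, "PointTargetScene"), is(geometry, "ScanGeometry"))
  g <- geometry
  samples <- matrix(0, nScans, nSamples)
  y <- (seq_len(nScans) - 1) * g@dz
  samplesPerUs <- g@fs * 1e-6
  # Gaussian tone-burst: sigma_t from the FWHM fractional bandwidth
  sigmaF <- scene@bandwidth * scene@f0 / (2 * sqrt(2 * log(2)))
  sigmaT <- 1 / (2 * pi * sigmaF) * 1e6           # us
  f0us <- scene@f0 * 1e-6                          # cycles per us

  tg <- scene@targets
  truth <- data.frame(target = seq_len(nrow(tg)), tg,
                      apex_scan = NA_integer_, arrival_sample = NA_real_,
                      half_width_mm = NA_real_, n_insonified = NA_integer_)
  for (k in seq_len(nrow(tg))) {
    lt <- tg$depth_mm[k]; et <- tg$elev_mm[k]; amp <- tg$amplitude[k]
    halfW <- abs(lt - g@lf) * g@w / (2 * g@lf)
    sgn <- sign(lt - g@lf)
    hit <- which(abs(y - et) <= halfW + 1e-12)
    apex <- which.min(abs(y - et))
    hit <- sort(unique(c(hit, apex)))
    nIns <- 0L
    for (i in hit) {
      path <- g@lf + sgn * sqrt((lt - g@lf)^2 + (y[i] - et)^2)  # mm
      tArr <- path / g@c                                        # us
      nArr <- g@n0 + (tArr - g@lf / g@c) * samplesPerUs         # 1-based
      if (nArr < 1 || nArr > nSamples)
        stop(sprintf("target %d arrives at sample %.1f, beyond the record",
                     k, nArr))
      win <- max(1, floor(nArr - 4 * sigmaT * samplesPerUs)):
             min(nSamples, ceiling(nArr + 4 * sigmaT * samplesPerUs))
      tRel <- (win - nArr) / samplesPerUs                       # us
      burst <- amp * exp(-tRel^2 / (2 * sigmaT^2)) * cos(2 * pi * f0us * tRel)
      samples[i, win] <- samples[i, win] + burst
      nIns <- nIns + 1L
    }
    truth$apex_scan[k] <- apex
    truth$arrival_sample[k] <- g@n0 + (abs(lt - g@lf) / g@c * sgn) * samplesPerUs
    truth$half_width_mm[k] <- halfW
    truth$n_insonified[k] <- nIns
  }
  if (scene@noiseSigma > 0) {
    samples <- samples + withr::with_seed(as.integer(scene@seed),
      matrix(rnorm(length(samples), sd = scene@noiseSigma), nScans, nSamples))
  }
  out <- AScanStack(samples, g)
  attr(out, "truth") <- truth
  out
}

#' Kinetic-movie scene
#'
#' @slot gridSize c(ny, nx) frame size in pixels.
#' @slot rois list; each element a list with `center` c(row, col), `radius`
#'   (px) and `params` ([EMMParams-class] ground truth).
#' @slot breathingPeriod respiration period (s).
#' @slot breathingAmplitude multiplicative spike factor (e.g. 1.5).
#' @slot breathingFraction fraction of frames affected (0 disables).
#' @slot noiseSigma additive Gaussian noise s.d. (intensity units).
#' @slot frameInterval seconds between frames.
#' @slot nFrames number of frames.
#' @slot baselineLevel pre-injection intensity inside ROIs and background.
#' @slot seed RNG seed.
#' @exportClass KineticScene
setClass("KineticScene",
  representation(gridSize = "integer", rois = "list",
                 breathingPeriod = "numeric", breathingAmplitude = "numeric",
                 breathingFraction = "numeric", noiseSigma = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 baselineLevel = "numeric", seed = "numeric"))

#' @param gridSize,rois,noiseSigma,frameInterval,nFrames,baselineLevel,seed
#'   see the class slots.
#' @param breathingPeriod,breathingAmplitude,breathingFraction respiration
#'   artifact model: multiplicative whole-frame spikes of the given factor,
#'   placed one per period and thinned/extended to the given fraction of
#'   frames. Defaults: 0.5 s, 1.5x, 10%.
#' @rdname KineticScene-class
#' @export
KineticScene <- function(gridSize, rois, breathingPeriod = 0.5,
                         breathingAmplitude = 1.5, breathingFraction = 0.1,
                         noiseSigma = 0, frameInterval = 0.5, nFrames = 100L,
                         baselineLevel = 100, seed = 1L) {
  new("KineticScene", gridSize = as.integer(gridSize), rois = rois,
      breathingPeriod = breathingPeriod,
      breathingAmplitude = breathingAmplitude,
      breathingFraction = breathingFraction, noiseSigma = noiseSigma,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      baselineLevel = baselineLevel, seed = as.numeric(seed))
}

.diskMask <- function(gridSize, center, radius) {
  rr <- row(matrix(0, gridSize[1], gridSize[2]))
  cc <- col(matrix(0, gridSize[1], gridSize[2]))
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Simulate a dynamic contrast movie with known kinetics
#'
#' Every ROI's pixels follow
#' `baselineLevel * (1 + RE_true(t) / 100)` with `RE_true` evaluated from
#' the ROI's ground-truth model parameters, so the extraction round trip
#' ([roiTimecourse()] then [relativeEnhancement()]) recovers the true curve
#' exactly in the noise-free case. Breathing artifacts are whole-frame
#' multiplicative spikes on a seeded, periodically placed subset of frames;
#' Gaussian noise is added last.
#'
#' @param scene a [KineticScene-class].
#' @return a [FrameSeries-class] with `attr(, "truth")` carrying the ROI
#'   masks, true parameters, true curves, baseline level and spike frames.
#' @export
makeKineticMovie <- function(scene) {
  stopifnot(is(scene, "KineticScene"))
  gs <- scene@gridSize
  nF <- scene@nFrames
  times <- (seq_len(nF) - 1) * scene@frameInterval

  masks <- lapply(scene@rois, function(r) .diskMask(gs, r$center, r$radius))
  if (length(masks) > 1) {
    for (a in seq_along(masks)) for (b in seq_len(a - 1L)) {
      if (any(masks[[a]] & masks[[b]]))
        stop("overlapping ROIs with conflicting kinetics")
    }
  }
  curves <- lapply(scene@rois, function(r) emmEvaluate(r$params, times))

  frames <- array(scene@baselineLevel, c(nF, gs[1], gs[2]))
  for (k in seq_along(masks)) {
    idx <- which(masks[[k]])
    for (f in seq_len(nF)) {
      sl <- frames[f, , ]
      sl[idx] <- scene@baselineLevel * (1 + curves[[k]][f] / 100)
      frames[f, , ] <- sl
    }
  }

  spikeFrames <- integer(0)
  nSpikes <- round(scene@breathingFraction * nF)
  if (nSpikes > 0 && scene@breathingAmplitude != 1) {
    periodic <- seq(2L, nF, by = max(1L, round(scene@breathingPeriod /
                                               scene@frameInterval)))
    spikeFrames <- withr::with_seed(as.integer(scene@seed) + 1L, {
      if (length(periodic) >= nSpikes) sort(sample(periodic, nSpikes))
      else sort(unique(c(periodic, sample(setdiff(seq(2L, nF), periodic),
                                          nSpikes - length(periodic)))))
    })
    for (f in spikeFrames)
      frames[f, , ] <- frames[f, , ] * scene@breathingAmplitude
  }

  if (scene@noiseSigma > 0) {
    frames <- frames + withr::with_seed(as.integer(scene@seed),
      array(rnorm(length(frames), sd = scene@noiseSigma), dim(frames)))
  }

  out <- FrameSeries(frames, scene@frameInterval)
  attr(out, "truth") <- list(masks = masks,
                             params = lapply(scene@rois, `[[`, "params"),
                             curves = curves, times = times,
                             baselineLevel = scene@baselineLevel,
                             spikeFrames = spikeFrames)
  out
}

#' Preset segmented optical tissue maps
#'
#' Literature-typical soft-tissue optical properties (not measured values):
#' \itemize{
#'   \item `absorbing-slab`: mu_a = 0.1 /mm, mu_s = 0 everywhere.
#'   \item `scattering-slab`: mu_a = 0.01 /mm, mu_s = 10 /mm, g = 0.9.
#'   \item `two-layer`: upper half mu_a = 0.02, lower half mu_a = 0.1
#'     (both mu_s = 5 /mm, g = 0.9); the boundary sits at half depth.
#'   \item `disk-inclusion`: scattering background with a circular
#'     high-absorption (mu_a = 0.3 /mm) disk of radius 1/6 grid at center;
#'     geometry attached as `attr(, "inclusion")`.
#' }
#'
#' @param preset one of the names above.
#' @param gridSize c(nz, nx) in cells.
#' @param spacing cell size (mm), default 0.5.
#' @return a [TissueModel-class].
#' @export
makeTissueMap <- function(preset = c("absorbing-slab", "scattering-slab",
                                     "two-layer", "disk-inclusion"),
                          gridSize = c(60L, 60L), spacing = 0.5) {
  preset <- match.arg(preset)
  nz <- gridSize[1]; nx <- gridSize[2]
  labels <- matrix(1L, nz, nx)
  inclusion <- NULL
  if (preset == "absorbing-slab") {
    muA <- 0.1; muS <- 0; g <- 0
  } else if (preset == "scattering-slab") {
    muA <- 0.01; muS <- 10; g <- 0.9
  } else if (preset == "two-layer") {
    labels[(nz %/% 2 + 1):nz, ] <- 2L
    muA <- c(0.02, 0.1); muS <- c(5, 5); g <- c(0.9, 0.9)
  } else {
    ctr <- c(nz / 2, nx / 2); rad <- min(nz, nx) / 6
    labels[.diskMask(c(nz, nx), ctr, rad)] <- 2L
    muA <- c(0.01, 0.3); muS <- c(10, 10); g <- c(0.9, 0.9)
    inclusion <- list(center = ctr, radius = rad)
  }
  out <- TissueModel(labels, muA, muS, g, spacing)
  if (!is.null(inclusion)) attr(out, "inclusion") <- inclusion
  out
}

# ring element positions (mm), centered on the origin
.ringElements <- function(radius, nElements) {
  th <- 2 * pi * (seq_len(nElements) - 1) / nElements
  cbind(x = radius * cos(th), y = radius * sin(th))
}

# pixel-center coordinates (mm) of an n x n grid centered on the origin
.gridCoords <- function(n, pixelSize) {
  (seq_len(n) - (n + 1) / 2) * pixelSize
}

#' Ring-array forward projection
#'
#' Discretized circular-arc integrals: each nonzero source pixel deposits
#' its value into the time bin of its one-way distance to each element.
#' Linear in the image by construction.
#'
#' @param image square source matrix (rows = y, cols = x), grid centered on
#'   the ring center.
#' @param radius ring radius (mm).
#' @param nElements number of ring elements.
#' @param fs sampling rate (Hz).
#' @param c speed of sound (mm/us).
#' @param pixelSize pixel edge (mm).
#' @param nSamples record length (default long enough for the whole grid).
#' @return matrix [element x time sample] of channel data.
#' @export
ringForward <- function(image, radius, nElements, fs, c = 1.5,
                        pixelSize = 0.1,
                        nSamples = NULL) {
  n <- nrow(image)
  stopifnot(ncol(image) == n)
  xs <- .gridCoords(n, pixelSize)
  maxExtent <- sqrt(2) * max(abs(xs))
  if (maxExtent >= radius) stop("image extends beyond the ring")
  if (is.null(nSamples))
    nSamples <- ceiling((radius + maxExtent) / c * fs * 1e-6) + 8L
  el <- .ringElements(radius, nElements)
  ch <- matrix(0, nElements, nSamples)
  nz <- which(image != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(ch)
  px <- xs[nz[, 2]]; py <- xs[nz[, 1]]; v <- image[nz]
  for (k in seq_len(nElements)) {
    d <- sqrt((px - el[k, 1])^2 + (py - el[k, 2])^2)
    bin <- round(d / c * fs * 1e-6) + 1L
    ok <- bin >= 1L & bin <= nSamples
    if (any(ok)) {
      acc <- tapply(v[ok], bin[ok], sum)
      ch[k, as.integer(names(acc))] <- ch[k, as.integer(names(acc))] + acc
    }
  }
  ch
}

#' Single-speed delay-and-sum ring-array back-projection
#'
#' For each output pixel, sums each element's channel sample at the one-way
#' propagation delay (nearest-sample lookup). The output grid is centered on
#' the ring center.
#'
#' @param channels matrix [element x time sample] from [ringForward()] or an
#'   acquisition.
#' @param radius ring radius (mm).
#' @param fs sampling rate (Hz).
#' @param c speed of sound (mm/us).
#' @param pixelSize output pixel edge (mm).
#' @param gridSize output grid side (pixels).
#' @return reconstructed image matrix [gridSize x gridSize].
#' @export
ringBackproject <- function(channels, radius, fs, c = 1.5, pixelSize = 0.1,
                            gridSize = 64L) {
  nElements <- nrow(channels); nSamples <- ncol(channels)
  xs <- .gridCoords(gridSize, pixelSize)
  px <- matrix(xs, gridSize, gridSize, byrow = TRUE)   # x by column
  py <- matrix(xs, gridSize, gridSize)                 # y by row
  el <- .ringElements(radius, nElements)
  img <- matrix(0, gridSize, gridSize)
  for (k in seq_len(nElements)) {
    d <- sqrt((px - el[k, 1])^2 + (py - el[k, 2])^2)
    bin <- round(d / c * fs * 1e-6) + 1L
    bin[bin < 1L | bin > nSamples] <- NA
    vals <- channels[k, ]
    add <- vals[bin]
    add[is.na(add)] <- 0
    img <- img + add
  }
  img / nElements
}
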