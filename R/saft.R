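#' Elevational spread half-extent of a defocused target
#'
#' A target at one-way depth `l` seen by a focused transducer (focal
#' distance `lf`, element height `w`) spreads over neighboring elevational
#' scans within `z = (l - lf) * w / (2 lf)`; the sign carries the defocus
#' direction (positive beyond the focus).
#'
#' @param l target depth(s), mm.
#' @param geometry a [ScanGeometry-class].
#' @return signed half-extent z (mm).
#' @examples
#' g <- ScanGeometry(lf = 20, w = 8, dz = 0.1, fs = 40e6, n0 = 400)
#' coherentHalfExtent(30, g)  # +2 mm
#' @export
coherentHalfExtent <- function(l, geometry) {
  stopifnot(is(geometry, "ScanGeometry"))
  (l - geometry@lf) * geometry@w / (2 * geometry@lf)
}

#' Number of coherent elevational layers
#'
#' @param z signed spread half-extent (mm), from [coherentHalfExtent()].
#' @param dz elevational step (mm).
#' @return `floor(|z| / dz)`, a nonnegative integer.
#' @export
coherentLayers <- function(z, dz) {
  if (dz <= 0) stop("dz must be > 0")
  as.integer(floor(abs(z) / dz))
}

#' Range from a sample to the acoustic focus
#'
#' @param ni 1-based sample index (vectorized).
#' @param geometry a [ScanGeometry-class].
#' @return `|n0 - ni| / fs * c`, mm.
#' @export
targetRange <- function(ni, geometry) {
  stopifnot(is(geometry, "ScanGeometry"))
  abs(geometry@n0 - ni) / geometry@fs * 1e6 * geometry@c
}

#' Inter-layer arrival-time delay
#'
#' Delay of the defocused arrival at elevational layer offset `j` relative
#' to the apex: `dt_j = sign * (sqrt(ri^2 + (j dz)^2) - ri) / c`, in
#' microseconds. `defocusSign` is the sign of `l - lf` (+1 beyond the
#' focus, -1 before it).
#'
#' @param ri range from sample to focus (mm).
#' @param j integer layer offset (vectorized).
#' @param geometry a [ScanGeometry-class].
#' @param defocusSign +1 or -1.
#' @return delay(s) in microseconds; 0 at `j = 0`.
#' @export
interlayerDelay <- function(ri, j, geometry, defocusSign = 1) {
  stopifnot(is(geometry, "ScanGeometry"), ri >= 0)
  rij <- sqrt(ri^2 + (j * geometry@dz)^2)
  defocusSign * (rij - ri) / geometry@c
}

#' @describeIn applySAFT refocus an elevational A-scan stack.
#'
#' For every pixel the coherent aperture is derived from its depth
#' ([coherentHalfExtent()], [coherentLayers()]); delayed neighbors
#' `j in [-floor(zs/2), floor(zs/2)]` are summed with fractional-delay
#' interpolation (aperture truncated at stack edges, never wrapped), and the
#' coherence factor `CF = PA_SAFT^2 / (norm * sum |PA|^2)` down-weights
#' incoherent contributions. With `cfNorm = "count"` (default) `norm` is the
#' number of terms actually summed and CF is bounded in [0, 1]; with
#' `cfNorm = "zs"` it is the layer count `z_s`, the conventional written
#' form, which exceeds 1 on fully coherent apertures (the count form is the
#' corrected default for that reason). Where the denominator vanishes
#' (empty or all-zero aperture, or `z_s = 0`) CF is 1 and the pixel passes
#' through unchanged.
#'
#' @param interp `"linear"` (fractional-delay interpolation, default) or
#'   `"nearest"`.
#' @param cfNorm `"count"` or `"zs"` (see Details).
#' @return a [SAFTResult-class].
#' @export
setMethod("applySAFT", "AScanStack",
          function(stack, interp = c("linear", "nearest"),
                   cfNorm = c("count", "zs"), ...) {
  interp <- match.arg(interp)
  cfNorm <- match.arg(cfNorm)
  g <- stack@geometry
  res <- .saftCpp(stack@samples, g@lf, g@w, g@dz, g@fs, g@c, g@n0,
                  as.integer(interp == "linear"),
                  as.integer(cfNorm == "count"))
  new("SAFTResult", paSaft = res$pa_saft, cf = res$cf,
      paCfSaft = res$pa_cfsaft)
})

#' Split a stack into low- and high-frequency bands
#'
#' Complementary zero-phase spectral masking along the time/depth axis:
#' the low band keeps Fourier components with `|f| <= fc`, the high band is
#' the exact remainder, so `low + high` reconstructs the input to floating
#' tolerance. In refocused photoacoustic volumes the high band carries
#' vascular signal and the low band slowly varying tissue/organ signal.
#'
#' @param volume numeric vector or matrix (time along columns for a matrix,
#'   i.e. [elevation x sample]).
#' @param fc cutoff frequency (Hz), 0 < fc < fs/2.
#' @param fs sampling rate (Hz).
#' @return `list(low = , high = )` with the shape of the input.
#' @export
bandSplit <- function(volume, fc, fs) {
  if (!is.finite(fc) || fc <= 0 || fc >= fs / 2)
    stop("cutoff must satisfy 0 < fc < fs/2")
  vec <- is.null(dim(volume))
  x <- if (vec) matrix(volume, nrow = 1) else volume
  n <- ncol(x)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)          # two-sided |f|
  mask <- as.numeric(freqs <= fc)
  X <- mvfft(t(x))
  low <- t(Re(mvfft(X * mask, inverse = TRUE))) / n
  high <- x - low
  if (vec) list(low = as.numeric(low), high = as.numeric(high))
  else list(low = low, high = high)
}

#' Envelope via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal along the time axis, computed by
#' the standard FFT construction (double positive frequencies, zero negative
#' ones).
#'
#' @param x numeric vector, or matrix with time along columns.
#' @return nonnegative array of the same shape.
#' @export
envelope <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  n <- ncol(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(t(m)) * h
  env <- t(Mod(mvfft(X, inverse = TRUE))) / n
  if (vec) as.numeric(env) else env
}

#' Full width at half maximum of a sampled profile
#'
#' Locates the half-maximum crossings on both sides of the unique global
#' peak by linear interpolation.
#'
#' @param profile sampled 1-D curve with a positive global maximum.
#' @param spacing sample spacing (any length unit).
#' @return the width in the units of `spacing`.
#' @examples
#' x <- seq(-5, 5, by = 0.01)
#' measureFWHM(exp(-x^2 / 2), 0.01)  # ~2.3548 (sigma = 1)
#' @export
measureFWHM <- function(profile, spacing = 1) {
  n <- length(profile)
  ipk <- which.max(profile)
  pk <- profile[ipk]
  if (!is.finite(pk) || pk <= 0) stop("profile must have a positive maximum")
  half <- pk / 2
  # left crossing
  left <- NA_real_
  if (ipk >= 2) for (i in ipk:2) {
    if (profile[i - 1] < half && profile[i] >= half) {
      left <- (i - 1) + (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  right <- NA_real_
  if (ipk < n) for (i in seq(ipk, n - 1)) {
    if (profile[i] >= half && profile[i + 1] < half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("no half-maximum crossing on one side of the peak")
  (right - left) * spacing
}
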