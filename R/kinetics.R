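#' @rdname relativeEnhancement
setMethod("relativeEnhancement", "ROITimeCourse", function(raw) {
  if (!identical(raw@kind, "raw-intensity"))
    stop("relativeEnhancement() expects a raw-intensity time course")
  if (is.na(raw@baselineValue) || raw@baselineValue <= 0)
    stop("invalid baseline: PA(0) must be a positive finite value")
  re <- 100 * (raw@values - raw@baselineValue) / raw@baselineValue
  ROITimeCourse(raw@times, re, baselineValue = raw@baselineValue,
                kind = "relative-enhancement")
})

#' Remove breathing outliers from an enhancement curve
#'
#' Respiratory motion produces isolated spikes in ROI time courses. They are
#' removed with a Hampel filter: a sample deviating from its running median
#' by more than `nMad` local scaled median absolute deviations is replaced by
#' that running median; all other samples are untouched.
#'
#' @param re a [ROITimeCourse-class] (any kind).
#' @param window odd window length in samples (default 11).
#' @param nMad threshold in local MAD units (default 3).
#' @return a filtered [ROITimeCourse-class] on the same times.
#' @examples
#' x <- rep(10, 20); x[8] <- 1000
#' tc <- ROITimeCourse(seq_along(x), x, kind = "relative-enhancement")
#' valuesOf(filterBreathingOutliers(tc))[8]
#' @export
filterBreathingOutliers <- function(re, window = 11L, nMad = 3) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  n <- length(re@times)
  if (n <= window)
    stop("insufficient data: series must be longer than the filter window")
  k <- (window - 1L) %/% 2L
  x <- re@values
  filtered <- x
  # truncated windows at the record ends so edge spikes are also caught
  for (i in seq_len(n)) {
    win <- x[max(1L, i - k):min(n, i + k)]
    med <- median(win)
    s <- 1.4826 * median(abs(win - med))
    if (abs(x[i] - med) > nMad * s) filtered[i] <- med
  }
  ROITimeCourse(re@times, filtered, baselineValue = re@baselineValue,
                kind = re@kind)
}

#' Evaluate the fluence-corrected empirical enhancement model
#'
#' The curve is 0 before the rise time point `t0` and
#' `(A/fRatio) * (1 - exp(-alpha (t - t0)))^q * exp(-beta (t - t0))`
#' afterwards; it is continuous at `t0`.
#'
#' @param params an [EMMParams-class].
#' @param times evaluation times (s).
#' @return relative enhancement values (%) at `times`.
#' @examples
#' p <- EMMParams(A = 100, t0 = 10, alpha = 0.2, beta = 0.01, q = 1)
#' emmEvaluate(p, 20)  # 100 * (1 - exp(-2)) * exp(-0.1)
#' @export
emmEvaluate <- function(params, times) {
  stopifnot(is(params, "EMMParams"))
  validObject(params)
  .emm(times, params@A, params@t0, params@alpha, params@beta, params@q,
       params@fRatio)
}

# vectorized model kernel on plain numerics (shared by fit and evaluate)
.emm <- function(t, A, t0, alpha, beta, q, fRatio) {
  s <- t - t0
  out <- numeric(length(t))
  up <- s >= 0
  out[up] <- (A / fRatio) * (1 - exp(-alpha * s[up]))^q * exp(-beta * s[up])
  out
}

#' Fit the empirical enhancement model to a relative-enhancement curve
#'
#' Bounded Levenberg-Marquardt least squares for (A, t0, alpha, beta, q);
#' the fluence ratio is a fixed, known scalar, not a free parameter.
#' Initialization: A from the observed peak (times fRatio), t0 from the first
#' sample exceeding 5% of the peak, beta from the log-linear slope of the
#' tail, alpha from the 10-90% rise time, q = 1. Up to `nStarts` restarts
#' with jittered initial values (seeded) are tried; the best converged
#' solution wins.
#'
#' @param re a relative-enhancement [ROITimeCourse-class] with >= 8 samples.
#' @param fRatio post/pre-injection fluence ratio (> 0), held fixed.
#' @param nStarts maximum number of jittered restarts (default 5).
#' @param seed RNG seed for the restart jitter.
#' @return an [EMMFit-class].
#' @examples
#' p <- EMMParams(A = 80, t0 = 5, alpha = 0.05, beta = 0.002, q = 1.5)
#' tt <- seq(0, 600, by = 1)
#' tc <- ROITimeCourse(tt, emmEvaluate(p, tt), kind = "relative-enhancement")
#' fitEMM(tc)
#' @export
fitEMM <- function(re, fRatio = 1, nStarts = 5L, seed = 1L) {
  stopifnot(is(re, "ROITimeCourse"))
  if (!identical(re@kind, "relative-enhancement"))
    stop("fitEMM() expects a relative-enhancement time course")
  if (length(re@times) < 8L) stop("need at least 8 samples to fit")
  if (!is.finite(fRatio) || fRatio <= 0) stop("fRatio must be > 0")
  y <- re@values
  t <- re@times
  if (all(y == 0)) stop("degenerate input: all-zero enhancement series")

  peak <- max(y)
  if (peak <= 0) stop("degenerate input: no positive enhancement")
  tPeak <- t[which.max(y)]

  lower <- c(A = 1e-8, t0 = min(t), alpha = 1e-6, beta = 0, q = 0.1)
  upper <- c(A = 10 * peak * fRatio, t0 = tPeak, alpha = 100, beta = 10,
             q = 10)

  init <- .emmInit(t, y, fRatio, tPeak, peak)
  init <- pmin(pmax(init, lower), upper)

  resid <- function(p) {
    .emm(t, p[["A"]], p[["t0"]], p[["alpha"]], p[["beta"]], p[["q"]],
         fRatio) - y
  }

  best <- NULL
  starts <- list(init)
  rng <- .seededRNG(seed)
  for (k in seq_len(max(0L, nStarts - 1L))) {
    jit <- init * exp(rng(5L, -0.35, 0.35))
    jit[["t0"]] <- init[["t0"]] * rng(1L, 0.5, 1.5)
    starts[[k + 1L]] <- pmin(pmax(jit, lower), upper)
  }
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    rss <- sum(fit$fvec^2)
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && rss < best$rss)) {
      best <- list(par = fit$par, rss = rss, ok = ok, fit = fit)
    }
    if (ok && rss <= 1e-16 * max(1, sum(y^2))) break
  }
  if (is.null(best)) stop("fit failed to produce any solution")

  covm <- tryCatch({
    v <- try(solve(best$fit$hessian) * best$rss /
               max(1L, length(y) - 5L), silent = TRUE)
    if (inherits(v, "try-error")) matrix(numeric(), 0, 0) else v
  }, error = function(e) matrix(numeric(), 0, 0))

  p <- best$par
  new("EMMFit",
      params = EMMParams(A = max(p[["A"]], 1e-12), t0 = max(p[["t0"]], 0),
                         alpha = max(p[["alpha"]], 1e-12),
                         beta = max(p[["beta"]], 0), q = p[["q"]],
                         fRatio = fRatio),
      rss = best$rss, nPoints = length(y), converged = isTRUE(best$ok),
      covariance = covm)
}

# heuristic initial values from the data
.emmInit <- function(t, y, fRatio, tPeak, peak) {
  t0 <- t[which(y > 0.05 * peak)[1]]
  if (is.na(t0)) t0 <- t[1]
  # tail slope for beta: log-linear fit on the post-peak segment
  tail_idx <- which(t > tPeak & y > 1e-3 * peak)
  beta <- 1e-3
  if (length(tail_idx) >= 3) {
    sl <- stats::coef(stats::lm(log(y[tail_idx]) ~ t[tail_idx]))[2]
    if (is.finite(sl) && sl < 0) beta <- -sl
  }
  # 10-90% rise time for alpha
  rise_idx <- which(t <= tPeak)
  t10 <- t[rise_idx][which(y[rise_idx] >= 0.1 * peak)[1]]
  t90 <- t[rise_idx][which(y[rise_idx] >= 0.9 * peak)[1]]
  alpha <- if (!is.na(t10) && !is.na(t90) && t90 > t10) 2.2 / (t90 - t10)
           else 1 / max(tPeak - t0, 1e-3)
  c(A = unname(peak * fRatio), t0 = unname(t0), alpha = unname(alpha),
    beta = unname(beta), q = 1)
}

# local uniform RNG that does not disturb the global .Random.seed
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(n, lo = 0, hi = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, globalenv())
    out <- runif(n, lo, hi)
    env$state <- get(".Random.seed", globalenv())
    out
  }
}

#' Derive clearance parameters from a fitted enhancement curve
#'
#' The peak time is the closed-form stationary point
#' `tMax = t0 + log((q alpha + beta) / beta) / alpha` for `beta > 0`
#' (clamped to `tEnd` when it falls beyond the analysis window); with
#' `beta == 0` the curve saturates monotonically and `tMax = tEnd`. The
#' elimination half-life `tHalf` is the elapsed time after `tMax` at which
#' the fitted curve falls to half its peak, found by root bracketing; it is
#' `Inf` when `beta == 0`. Rates are reported in 1/min (`uAlpha = 60 alpha`,
#' `eBeta = 60 beta`). The AUC integrates the fitted curve over
#' `[0, tEnd]` by adaptive quadrature.
#'
#' @param fit a converged [EMMFit-class].
#' @param tEnd right end of the analysis window (s), > t0.
#' @return a [ClearanceSummary-class].
#' @examples
#' p <- EMMParams(A = 100, t0 = 10, alpha = 0.2, beta = 0.01, q = 1)
#' f <- new("EMMFit", params = p, rss = 0, nPoints = 100L, converged = TRUE)
#' clearanceSummary(f, tEnd = 600)
#' @export
clearanceSummary <- function(fit, tEnd) {
  stopifnot(is(fit, "EMMFit"))
  if (!fit@converged) stop("clearanceSummary() requires a converged fit")
  p <- fit@params
  if (tEnd <= p@t0) stop("tEnd must exceed the rise time point t0")

  if (p@beta > 0) {
    tMax <- p@t0 + log((p@q * p@alpha + p@beta) / p@beta) / p@alpha
    tMax <- min(tMax, tEnd)
  } else {
    tMax <- tEnd
  }
  peak <- emmEvaluate(p, tMax)

  if (p@beta > 0) {
    target <- function(t) emmEvaluate(p, t) - 0.5 * peak
    hi <- tMax + log(2) / p@beta  # at least the pure-exponential half-life
    while (target(hi) > 0) hi <- tMax + 2 * (hi - tMax)
    tHalf <- uniroot(target, c(tMax, hi), tol = 1e-9)$root - tMax
  } else {
    tHalf <- Inf
  }

  auc <- integrate(function(t) emmEvaluate(p, t), lower = 0, upper = tEnd,
                   subdivisions = 2000L, rel.tol = 1e-9)$value

  new("ClearanceSummary",
      reMaxAmplitude = p@A / p@fRatio, reMaxCurve = peak, tMax = tMax,
      tHalf = tHalf, uAlpha = 60 * p@alpha, eBeta = 60 * p@beta,
      auc = auc, tEnd = tEnd)
}

#' Trapezoid AUC of the raw samples
#'
#' Companion to the fitted-curve AUC in [clearanceSummary()]: integrates the
#' observed samples directly by the trapezoid rule over `[min(times), tEnd]`.
#'
#' @param re a [ROITimeCourse-class].
#' @param tEnd right end of the window (s); samples beyond it are dropped.
#' @return the trapezoid integral (%*s).
#' @export
rawAUC <- function(re, tEnd = max(re@times)) {
  keep <- re@times <= tEnd
  t <- re@times[keep]; y <- re@values[keep]
  if (length(t) < 2L) stop("need at least 2 samples within the window")
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}
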