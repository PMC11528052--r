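#' Read a time course from CSV
#'
#' Expects a header with columns `time_s` and `value`.
#'
#' @param path CSV file path.
#' @param kind `"raw-intensity"` or `"relative-enhancement"`.
#' @param baselineValue PA(0) for raw-intensity courses.
#' @return a [ROITimeCourse-class].
#' @export
readTimeCourse <- function(path, kind = "raw-intensity",
                           baselineValue = NA_real_) {
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("CSV must have columns time_s and value")
  ROITimeCourse(df$time_s, df$value, baselineValue = baselineValue,
                kind = kind)
}

#' Write a time course to CSV
#'
#' @param tc a [ROITimeCourse-class].
#' @param path output CSV path (columns `time_s`, `value`).
#' @return `path`, invisibly.
#' @export
writeTimeCourse <- function(tc, path) {
  write.csv(data.frame(time_s = tc@times, value = tc@values), path,
            row.names = FALSE)
  invisible(path)
}

#' Write a fit and its clearance summary as JSON
#'
#' @param fit an [EMMFit-class].
#' @param summary the matching [ClearanceSummary-class] (optional).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeFitJSON <- function(fit, summary = NULL, path) {
  p <- fit@params
  out <- list(A = p@A, t0_s = p@t0, alpha_per_s = p@alpha,
              beta_per_s = p@beta, q = p@q, f_ratio = p@fRatio,
              converged = fit@converged, rss = fit@rss)
  if (!is.null(summary)) {
    s <- as.list(summary)
    if (!is.finite(s$t_half_s)) s$t_half_s <- NULL  # undefined sentinel
    out <- c(out, s)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an array container (A-scan stack, frame series, fluence map,
#' tissue model) to an Arrow IPC file
#'
#' Arrays are stored flattened (column-major) in an Arrow/Feather file with
#' the object's metadata — attribute names carry the units (`fs_hz`,
#' `dz_mm`, `c_mm_per_us`, ...) — embedded in the file; the round trip is
#' lossless for doubles.
#'
#' @param x an [AScanStack-class], [FrameSeries-class], [FluenceMap-class]
#'   or [TissueModel-class].
#' @param path output file path (conventionally `.feather`).
#' @return `path`, invisibly.
#' @export
writeStack <- function(x, path) {
  if (is(x, "AScanStack")) {
    g <- x@geometry
    df <- data.frame(data = as.numeric(x@samples))
    meta <- list(type = "AScanStack", dims = dim(x@samples),
                 fs_hz = g@fs, dz_mm = g@dz, lf_mm = g@lf, w_mm = g@w,
                 c_mm_per_us = g@c, n0 = g@n0)
  } else if (is(x, "FrameSeries")) {
    df <- data.frame(data = as.numeric(x@frames))
    meta <- list(type = "FrameSeries", dims = dim(x@frames),
                 frame_interval_s = x@frameInterval, pixel_mm = x@pixelSize)
  } else if (is(x, "FluenceMap")) {
    df <- data.frame(data = as.numeric(x@values))
    meta <- list(type = "FluenceMap", dims = dim(x@values),
                 n_photons = x@nPhotons, seed = x@seed)
  } else if (is(x, "TissueModel")) {
    df <- data.frame(data = as.numeric(x@labels))
    meta <- list(type = "TissueModel", dims = dim(x@labels),
                 spacing_mm = x@spacing, mu_a_per_mm = x@muA,
                 mu_s_per_mm = x@muS, g = x@g)
  } else stop("unsupported object type: ", class(x))
  attr(df, "stack_meta") <- meta
  arrow::write_feather(df, path)
  invisible(path)
}

#' Read an array container written by [writeStack()]
#'
#' Validates the embedded metadata against the container type's contract
#' and errors naming any missing attribute.
#'
#' @param path file written by [writeStack()].
#' @return the reconstructed object.
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- arrow::read_feather(path)
  meta <- attr(df, "stack_meta")
  if (is.null(meta) || is.null(meta$type) || is.null(meta$dims))
    stop("corrupt container: missing stack_meta")
  required <- switch(meta$type,
    AScanStack = c("fs_hz", "dz_mm", "lf_mm", "w_mm", "c_mm_per_us", "n0"),
    FrameSeries = c("frame_interval_s", "pixel_mm"),
    FluenceMap = c("n_photons", "seed"),
    TissueModel = c("spacing_mm", "mu_a_per_mm", "mu_s_per_mm", "g"),
    stop("unknown container type: ", meta$type))
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("validation error: missing required attribute(s): ",
         paste(missing, collapse = ", "))
  dat <- as.numeric(df$data)
  switch(meta$type,
    AScanStack = AScanStack(
      matrix(dat, meta$dims[1], meta$dims[2]),
      ScanGeometry(lf = meta$lf_mm, w = meta$w_mm, dz = meta$dz_mm,
                   fs = meta$fs_hz, c = meta$c_mm_per_us, n0 = meta$n0)),
    FrameSeries = FrameSeries(array(dat, meta$dims),
                              frameInterval = meta$frame_interval_s,
                              pixelSize = meta$pixel_mm),
    FluenceMap = new("FluenceMap",
                     values = matrix(dat, meta$dims[1], meta$dims[2]),
                     nPhotons = meta$n_photons, seed = meta$seed),
    TissueModel = TissueModel(matrix(as.integer(dat), meta$dims[1],
                                     meta$dims[2]),
                              meta$mu_a_per_mm, meta$mu_s_per_mm, meta$g,
                              meta$spacing_mm))
}

#' Write a frame series as a multi-page TIFF
#'
#' Pixel values are stored as 32-bit floats; the frame interval and pixel
#' size go into a JSON sidecar (`<path>.json`).
#'
#' @param series a [FrameSeries-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeFrameSeriesTIFF <- function(series, path) {
  d <- dim(series@frames)
  pages <- lapply(seq_len(d[1]), function(k) series@frames[k, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(frame_interval_s = series@frameInterval,
                            pixel_mm = series@pixelSize),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF frame series
#'
#' @param path TIFF written by [writeFrameSeriesTIFF()]; the sidecar
#'   `<path>.json` supplies the timing metadata (or pass it explicitly).
#' @param frameInterval,pixelSize override the sidecar values.
#' @return a [FrameSeries-class].
#' @export
readFrameSeriesTIFF <- function(path, frameInterval = NULL,
                                pixelSize = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(frameInterval)) frameInterval <- meta$frame_interval_s
    if (is.null(pixelSize)) pixelSize <- meta$pixel_mm
  }
  if (is.null(frameInterval))
    stop("validation error: missing required attribute(s): frame_interval_s")
  if (is.null(pixelSize)) pixelSize <- 0.025
  frames <- array(0, c(length(pages), dim(pages[[1]])))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]]
  FrameSeries(frames, frameInterval, pixelSize)
}

#' Read a PNG mask as an ROI
#'
#' Any pixel with value > 0.5 (first channel) is inside the region.
#'
#' @param path PNG file.
#' @param label region name.
#' @return an [ROIMask-class].
#' @export
readROIMaskPNG <- function(path, label = basename(path)) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  ROIMask(img > 0.5, label = label)
}
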