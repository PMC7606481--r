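#' DSA frame sequence
#'
#' Container for a digital-subtraction-angiography cine run: a stack of 2-D
#' frames with a strictly increasing time axis. Frames are stored as an
#' `(H, W, T)` array (`frames[, , k]` is frame `k`); times are frame midpoint
#' times in seconds, acquisition-relative (the first time may be nonzero).
#'
#' @param frames numeric array of dimension `(H, W, T)`, arbitrary intensity
#'   units. `T >= 3`.
#' @param times numeric vector of length `T`, strictly increasing, seconds.
#' @param view one of `"AP"`, `"LAT"`, `"UNKNOWN"` (projection of a biplane
#'   acquisition).
#' @param pixel_spacing_mm optional positive length-2 numeric (row, col)
#'   spacing in millimetres.
#' @param source_id free-text provenance tag.
#' @return an object of class `FrameSequence`.
#' @export
frame_sequence <- function(frames, times, view = "UNKNOWN",
                           pixel_spacing_mm = NULL, source_id = "") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    .stopf("`frames` must be a 3-D (H, W, T) array")
  nt <- dim(frames)[3L]
  if (nt < 3L) .stopf("a frame sequence needs at least 3 frames, got %d", nt)
  if (length(times) != nt)
    .stopf("length(times) [%d] must equal the frame count [%d]", length(times), nt)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    .stopf("`times` must be finite and strictly increasing")
  view <- match.arg(view, VIEWS)
  if (!is.null(pixel_spacing_mm)) {
    if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
      .stopf("`pixel_spacing_mm` must be a positive (row, col) pair")
  }
  structure(
    list(frames = frames, times = as.numeric(times), view = view,
         pixel_spacing_mm = pixel_spacing_mm, source_id = source_id),
    class = "FrameSequence")
}

#' @export
print.FrameSequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<FrameSequence> %dx%d px, %d frames, t = [%.3f, %.3f] s, view %s\n",
              d[1], d[2], d[3], x$times[1], x$times[length(x$times)], x$view))
  invisible(x)
}

#' Baseline-corrected contrast-proxy stack
#'
#' Holds \eqn{C_{x,y}(t)}: the nonnegative per-pixel contrast proxy obtained
#' by subtracting the per-pixel baseline from the raw frames (see
#' [to_contrast()]). Also carries the per-pixel baseline-window standard
#' deviation used for the pixel-validity noise floor.
#'
#' @param contrast `(H, W, T)` array, all values `>= 0`.
#' @param times as in [frame_sequence()].
#' @param baseline_frames number of leading frames averaged into the baseline
#'   (`>= 1`, `< T`).
#' @param polarity `"DARK_CONTRAST"` (DSA convention, iodine darkens the
#'   subtracted image) or `"BRIGHT_CONTRAST"`.
#' @param baseline_sd optional `(H, W)` matrix of baseline-window standard
#'   deviations (intensity units).
#' @param view projection enum, carried through from the source sequence.
#' @return an object of class `ContrastSequence`.
#' @export
contrast_sequence <- function(contrast, times, baseline_frames, polarity,
                              baseline_sd = NULL, view = "UNKNOWN") {
  if (!is.array(contrast) || length(dim(contrast)) != 3L)
    .stopf("`contrast` must be a 3-D (H, W, T) array")
  nt <- dim(contrast)[3L]
  if (length(times) != nt || any(diff(times) <= 0))
    .stopf("`times` must match the frame count and be strictly increasing")
  if (min(contrast) < 0) .stopf("contrast values must be >= 0 (clamp after baseline subtraction)")
  if (!.is_count(baseline_frames) || baseline_frames < 1L || baseline_frames >= nt)
    .stopf("`baseline_frames` must be an integer in [1, T-1]")
  polarity <- match.arg(polarity, c("DARK_CONTRAST", "BRIGHT_CONTRAST"))
  structure(
    list(contrast = contrast, times = as.numeric(times),
         baseline_frames = as.integer(baseline_frames), polarity = polarity,
         baseline_sd = baseline_sd, view = match.arg(view, VIEWS)),
    class = "ContrastSequence")
}

#' Time-intensity curve of a single pixel or region
#'
#' @param times seconds, strictly increasing.
#' @param values contrast-proxy values, same length, `>= 0`.
#' @return an object of class `TimeIntensityCurve`.
#' @export
time_intensity_curve <- function(times, values) {
  if (length(times) != length(values))
    .stopf("`times` and `values` must have equal length")
  if (any(diff(times) <= 0)) .stopf("`times` must be strictly increasing")
  if (any(values < 0)) .stopf("curve values must be >= 0")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "TimeIntensityCurve")
}

#' Arterial input function curve
#'
#' The averaged contrast curve along a user-placed line spanning the injected
#' vessel, with its line-ROI provenance.
#'
#' @param curve a [time_intensity_curve()] with a strictly positive peak.
#' @param endpoints_px 2x2 matrix of 1-based (row, col) endpoints.
#' @param n_samples number of points sampled along the line (`>= 2`).
#' @return an object of class `AIFCurve`.
#' @export
aif_curve <- function(curve, endpoints_px, n_samples) {
  stopifnot(inherits(curve, "TimeIntensityCurve"))
  if (max(curve$values) <= 0) .stopf("AIF curve must have a strictly positive peak")
  endpoints_px <- matrix(as.numeric(endpoints_px), 2L, 2L)
  if (!.is_count(n_samples) || n_samples < 2L) .stopf("`n_samples` must be an integer >= 2")
  structure(list(curve = curve, endpoints_px = endpoints_px,
                 n_samples = as.integer(n_samples)),
            class = "AIFCurve")
}

#' Vascular-territory ROI mask
#'
#' @param mask logical `(H, W)` matrix with at least one `TRUE` pixel.
#' @param label one of `"MCA"`, `"ACA"`, `"PCA"`, `"VERTEBROBASILAR"`,
#'   `"CUSTOM"`.
#' @param view projection enum.
#' @return an object of class `ROIMask`.
#' @export
roi_mask <- function(mask, label = "CUSTOM", view = "UNKNOWN") {
  if (!is.matrix(mask) || !is.logical(mask)) .stopf("`mask` must be a logical matrix")
  if (!any(mask)) .stopf("ROI mask has no pixels")
  structure(list(mask = mask, label = match.arg(label, ROI_LABELS),
                 view = match.arg(view, VIEWS)),
            class = "ROIMask")
}

#' Co-registered perfusion parameter maps
#'
#' Six scalar maps (AT, TTP, TTD, MTT, CBV, CBF) on the frame raster plus a
#' validity mask. Invalid pixels carry `NaN` in every metric map — never 0,
#' so an invalid pixel can never masquerade as "instant arrival".
#'
#' @param maps named list of `(H, W)` numeric matrices, names
#'   `r paste(PERFUSION_METRICS, collapse = ", ")`.
#' @param validity_mask logical `(H, W)` matrix; `FALSE` wherever any metric
#'   is `NaN`.
#' @param times_window length-2 numeric `(t_start, t_end)` integration window
#'   in seconds.
#' @param view projection enum.
#' @param meta optional list of computation metadata (thresholds,
#'   conventions), serialized alongside the maps.
#' @return an object of class `PerfusionMapSet`.
#' @export
perfusion_map_set <- function(maps, validity_mask, times_window,
                              view = "UNKNOWN", meta = list()) {
  if (!all(PERFUSION_METRICS %in% names(maps)))
    .stopf("`maps` must contain all of: %s", paste(PERFUSION_METRICS, collapse = ", "))
  dims <- unique(lapply(maps[PERFUSION_METRICS], dim))
  if (length(dims) != 1L) .stopf("all metric maps must share one shape")
  if (!identical(dim(validity_mask), dims[[1L]]))
    .stopf("validity mask shape must match the metric maps")
  # enforce: invalid pixels sentinel-valued everywhere, mask false where any NaN
  any_nan <- Reduce(`|`, lapply(maps[PERFUSION_METRICS], function(m) !is.finite(m)))
  validity_mask <- validity_mask & !any_nan
  for (m in PERFUSION_METRICS) maps[[m]][!validity_mask] <- NaN
  structure(
    list(maps = maps[PERFUSION_METRICS], validity_mask = validity_mask,
         times_window = as.numeric(times_window),
         view = match.arg(view, VIEWS), meta = meta),
    class = "PerfusionMapSet")
}

#' @export
print.PerfusionMapSet <- function(x, ...) {
  d <- dim(x$validity_mask)
  cat(sprintf("<PerfusionMapSet> %dx%d px, %d valid (%.1f%%), window [%.2f, %.2f] s, view %s\n",
              d[1], d[2], sum(x$validity_mask),
              100 * mean(x$validity_mask),
              x$times_window[1], x$times_window[2], x$view))
  invisible(x)
}
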