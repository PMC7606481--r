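#' Rigid translation between two frames by phase correlation
#'
#' Estimates the integer-pixel (dy, dx) translation that maps `ref` onto
#' `mov` from the peak of the inverse FFT of the normalized cross-power
#' spectrum. Whole-pixel precision, which is sufficient for a motion
#' *screening* score (the pipeline excludes rather than corrects motion).
#'
#' @param ref,mov numeric matrices of identical shape.
#' @return numeric `(dy, dx)` in pixels, signed.
#' @export
phase_correlation_shift <- function(ref, mov) {
  stopifnot(identical(dim(ref), dim(mov)))
  Fa <- stats::fft(ref)
  Fb <- stats::fft(mov)
  R <- Fa * Conj(Fb)
  mag <- Mod(R)
  mag[mag < .Machine$double.eps] <- 1
  r <- Re(stats::fft(R / mag, inverse = TRUE))
  ij <- which(r == max(r), arr.ind = TRUE)[1L, ]
  d <- dim(ref)
  dy <- ij[1L] - 1L
  dx <- ij[2L] - 1L
  if (dy > d[1L] / 2) dy <- dy - d[1L]
  if (dx > d[2L] / 2) dx <- dx - d[2L]
  # peak at lag L means mov is ref shifted by -L under this correlation sign;
  # return the shift of mov relative to ref
  c(dy = -dy, dx = -dx)
}

#' Motion score of a sequence from its contrast-free baseline frames
#'
#' Median magnitude of the phase-correlation translation between consecutive
#' frames of the baseline (pre-injection) window. Contrast arrival itself
#' changes intensity and would confound registration metrics, hence the
#' restriction to baseline frames.
#'
#' @param seq a [frame_sequence()].
#' @param baseline_frames number of leading contrast-free frames to use
#'   (at least 2).
#' @return median per-frame translation magnitude in pixels.
#' @export
motion_score <- function(seq, baseline_frames = 5L) {
  nb <- min(as.integer(baseline_frames), dim(seq$frames)[3L])
  if (nb < 2L) .stopf("motion score needs at least 2 baseline frames")
  mags <- vapply(seq_len(nb - 1L), function(k) {
    s <- phase_correlation_shift(seq$frames[, , k], seq$frames[, , k + 1L])
    sqrt(sum(s^2))
  }, numeric(1))
  stats::median(mags)
}

#' Quality-control checks on a pre/post study pair
#'
#' Automates the study-exclusion rules as four checks: (a) same projection
#' view, (b) same geometry ("magnification" proxy: identical frame shape and,
#' when present, pixel spacing within 1%), (c) patient motion below a
#' threshold (median per-frame rigid translation over the baseline window of
#' either study), and (d) full bolus transit captured: each study's
#' frame-mean contrast curve returns below a configured fraction of its peak
#' before the last frame.
#'
#' A mismatch in frame *counts* alone is not an error: the two studies are
#' analyzed on their own time axes.
#'
#' @param pre,post [frame_sequence()] objects.
#' @param tol_cfg list of tolerances; recognised keys and defaults:
#'   `motion_threshold_px = 2`, `baseline_frames = 5`, `spacing_rtol = 0.01`,
#'   `transit_frac = 0.2`, `polarity = "DARK_CONTRAST"`.
#' @return a `QCReport` list: per check one pass flag and one scalar, plus an
#'   overall `pass`.
#' @export
validate_pair <- function(pre, post, tol_cfg = list()) {
  cfg <- utils::modifyList(list(
    motion_threshold_px = 2.0, baseline_frames = 5L,
    spacing_rtol = 0.01, transit_frac = 0.2,
    polarity = "DARK_CONTRAST"), tol_cfg)

  view_ok <- identical(pre$view, post$view)

  same_shape <- identical(dim(pre$frames)[1:2], dim(post$frames)[1:2])
  spacing_rel <- NA_real_
  spacing_ok <- TRUE
  if (!is.null(pre$pixel_spacing_mm) && !is.null(post$pixel_spacing_mm)) {
    spacing_rel <- max(abs(pre$pixel_spacing_mm - post$pixel_spacing_mm) /
                         pre$pixel_spacing_mm)
    spacing_ok <- spacing_rel <= cfg$spacing_rtol
  }
  shape_ok <- same_shape && spacing_ok

  ms <- max(motion_score(pre, cfg$baseline_frames),
            motion_score(post, cfg$baseline_frames))
  motion_ok <- ms < cfg$motion_threshold_px

  transit <- vapply(list(pre, post), function(s) {
    cs <- to_contrast(s, cfg$polarity, cfg$baseline_frames)
    g <- apply(cs$contrast, 3L, mean)
    if (max(g) <= 0) return(NA_real_)
    g[length(g)] / max(g)
  }, numeric(1))
  transit_ratio <- if (all(is.na(transit))) NA_real_ else max(transit, na.rm = TRUE)
  transit_ok <- !is.na(transit_ratio) && transit_ratio < cfg$transit_frac

  rpt <- list(
    view = list(pass = view_ok, value = paste(pre$view, post$view, sep = "/")),
    shape = list(pass = shape_ok, value = spacing_rel),
    motion = list(pass = motion_ok, value = ms),
    transit = list(pass = transit_ok, value = transit_ratio),
    pass = view_ok && shape_ok && motion_ok && transit_ok,
    config = cfg)
  class(rpt) <- "QCReport"
  rpt
}

#' @export
print.QCReport <- function(x, ...) {
  for (k in c("view", "shape", "motion", "transit")) {
    cat(sprintf("  %-8s %s  (%s)\n", k,
                if (isTRUE(x[[k]]$pass)) "PASS" else "FAIL",
                paste(format(x[[k]]$value, digits = 4), collapse = " ")))
  }
  cat(if (isTRUE(x$pass)) "QC: PASS\n" else "QC: FAIL\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `QCReport`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(report, path) {
  out <- list(
    view = list(pass = report$view$pass, views = report$view$value),
    shape = list(pass = report$shape$pass, spacing_rel = report$shape$value),
    motion = list(pass = report$motion$pass, score_px = report$motion$value),
    transit = list(pass = report$transit$pass, end_over_peak = report$transit$value),
    pass = report$pass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
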