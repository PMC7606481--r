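#' Bilinear interpolation of a 2-D image at sub-pixel points
#'
#' Coordinates are 1-based pixel centers: `(r, c) = (1, 1)` is the center of
#' the top-left pixel. Points are clamped to the valid interpolation domain.
#'
#' @param img numeric matrix.
#' @param r,cc numeric vectors of (row, col) coordinates.
#' @return interpolated values.
#' @keywords internal
.bilinear <- function(img, r, cc) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H)
  cc <- pmin(pmax(cc, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(cc), W - 1L)
  fr <- r - r0; fc <- cc - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Extract the arterial input function along a vessel-spanning line
#'
#' Builds \eqn{C_{AIF}(t)} as the per-frame mean of the contrast stack
#' sampled at evenly spaced points along a user-placed segment spanning the
#' width of the injected vessel. Sub-pixel sampling uses bilinear
#' interpolation, since vessel widths are only a few pixels. The AIF is
#' placed manually by the operator; automatic vessel segmentation is
#' deliberately out of scope.
#'
#' @param cs a [contrast_sequence()].
#' @param p0,p1 line endpoints, 1-based `(row, col)`; must differ and lie
#'   within the frame.
#' @param n_samples number of points along the segment; default
#'   `ceil(length in px) + 1`.
#' @return an [aif_curve()].
#' @export
extract_aif <- function(cs, p0, p1, n_samples = NULL) {
  stopifnot(inherits(cs, "ContrastSequence"))
  d <- dim(cs$contrast)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  for (p in list(p0, p1)) {
    if (length(p) != 2L || p[1L] < 1 || p[1L] > d[1L] || p[2L] < 1 || p[2L] > d[2L])
      .stopf("AIF endpoints must be (row, col) within the %dx%d frame", d[1L], d[2L])
  }
  if (all(p0 == p1)) .stopf("AIF endpoints must differ")
  len <- sqrt(sum((p1 - p0)^2))
  if (is.null(n_samples)) n_samples <- ceiling(len) + 1L
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) .stopf("`n_samples` must be >= 2")
  s <- seq(0, 1, length.out = n_samples)
  rr <- p0[1L] + s * (p1[1L] - p0[1L])
  cc <- p0[2L] + s * (p1[2L] - p0[2L])
  vals <- vapply(seq_len(d[3L]), function(k)
    mean(.bilinear(cs$contrast[, , k], rr, cc)), numeric(1))
  if (max(vals) <= 0) .stopf("AIF line sees no contrast: check endpoint placement")
  aif_curve(time_intensity_curve(cs$times, pmax(vals, 0)),
            endpoints_px = rbind(p0, p1), n_samples = n_samples)
}
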