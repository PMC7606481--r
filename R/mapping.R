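#' The perfusion colormap lookup table
#'
#' A 256-entry red-yellow-blue-black lookup table shipped with the package
#' (`inst/extdata/perfusion_lut.csv`). Only the endpoint semantics are
#' fixed by convention — red means increased perfusion, blue/black decreased
#' — so timing maps traverse it low-to-high and flow maps high-to-low (see
#' [render_map()]).
#'
#' @return 256 x 3 integer matrix of 8-bit R, G, B values.
#' @export
perfusion_lut <- function() {
  f <- system.file("extdata", "perfusion_lut.csv", package = "angioperf")
  lut <- as.matrix(utils::read.csv(f))
  storage.mode(lut) <- "integer"
  lut
}

#' Joint normalization bounds for a pre/post map pair
#'
#' Robust percentile bounds of the pooled valid pixels of both studies, so
#' that the two maps are colored on one shared scale. Robust (2nd/98th
#' percentile) rather than min/max because subtraction noise produces
#' extreme outliers that would crush the display range.
#'
#' @param pre,post [perfusion_map_set()] objects.
#' @param metric one of `r paste(PERFUSION_METRICS, collapse = ", ")`.
#' @param robust_pct length-2 percentiles in `[0, 100]` (default `c(2, 98)`).
#' @return numeric `(lo, hi)`.
#' @export
joint_normalize <- function(pre, post, metric, robust_pct = c(2, 98)) {
  metric <- match.arg(metric, PERFUSION_METRICS)
  pool <- c(pre$maps[[metric]][pre$validity_mask],
            post$maps[[metric]][post$validity_mask])
  if (!length(pool)) .stopf("no valid pixels to normalize for metric '%s'", metric)
  q <- stats::quantile(pool, probs = robust_pct / 100, names = FALSE, type = 7L)
  c(lo = q[1L], hi = q[2L])
}

#' Render one parametric map as a colorized RGB image
#'
#' Values are affinely mapped from `bounds` to the 256-entry LUT. Timing
#' metrics (AT, TTP, TTD, MTT) traverse the LUT low-to-high so that *low*
#' values (fast transit = good perfusion) are red; flow metrics (CBV, CBF)
#' use the reversed orientation so that *high* values are red. Red therefore
#' always indicates increased perfusion. Invalid pixels render black.
#'
#' @param map2d numeric `(H, W)` matrix (`NaN` = invalid).
#' @param bounds `(lo, hi)` from [joint_normalize()].
#' @param metric metric name (selects the LUT orientation).
#' @param lut optional LUT matrix (default [perfusion_lut()]).
#' @return `(H, W, 3)` numeric array in `[0, 1]`, with attribute `meta` =
#'   list(metric, lo, hi, orientation).
#' @export
render_map <- function(map2d, bounds, metric, lut = perfusion_lut()) {
  metric <- match.arg(metric, PERFUSION_METRICS)
  orientation <- if (metric %in% c("cbv", "cbf")) "high_is_red" else "low_is_red"
  lo <- bounds[1L]; hi <- bounds[2L]
  u <- (map2d - lo) / max(hi - lo, .Machine$double.eps)
  u[u < 0] <- 0; u[u > 1] <- 1
  if (orientation == "high_is_red") u <- 1 - u
  idx <- as.integer(round(u * (nrow(lut) - 1L))) + 1L
  bad <- !is.finite(map2d)
  idx[bad] <- 1L                       # placeholder, overwritten with black
  H <- nrow(map2d); W <- ncol(map2d)
  rgb <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    plane <- lut[idx, ch] / 255
    plane[bad] <- 0
    rgb[, , ch] <- plane
  }
  attr(rgb, "meta") <- list(metric = metric, lo = unname(lo), hi = unname(hi),
                            orientation = orientation)
  rgb
}

#' Invert a rendered map back to normalized values through the LUT
#'
#' Nearest-entry LUT lookup; used to verify that rendering is invertible to
#' within one LUT step.
#'
#' @param rgb `(H, W, 3)` array in `[0, 1]`.
#' @param lut LUT matrix.
#' @return `(H, W)` matrix of normalized values in `[0, 1]`.
#' @export
unrender_map <- function(rgb, lut = perfusion_lut()) {
  H <- dim(rgb)[1L]; W <- dim(rgb)[2L]
  px <- matrix(rgb, H * W, 3L) * 255
  d2 <- outer(rowSums(px^2), rowSums(lut^2), `+`) - 2 * px %*% t(lut)
  idx <- max.col(-d2, ties.method = "first")
  matrix((idx - 1L) / (nrow(lut) - 1L), H, W)
}

#' Write a rendered map to PNG with a JSON sidecar
#'
#' @param rgb output of [render_map()].
#' @param path PNG path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_rendered_map <- function(rgb, path) {
  png::writePNG(rgb, path)
  jsonlite::write_json(attr(rgb, "meta"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compose the four-panel pre/post review figure for one metric
#'
#' A 2x2 grid in clockwise order from top-left — pre-AP, pre-LAT, post-LAT,
#' post-AP — rendered under joint normalization with a shared vertical
#' colorbar on the right.
#'
#' @param pre_maps,post_maps named lists with `AP` and `LAT`
#'   [perfusion_map_set()] entries (either view may be `NULL`; missing
#'   panels render black).
#' @param metric metric to display.
#' @param robust_pct percentile bounds, see [joint_normalize()].
#' @param lut LUT matrix.
#' @return `(2H, 2W + bar, 3)` RGB array with `meta` attribute.
#' @export
compose_panel <- function(pre_maps, post_maps, metric, robust_pct = c(2, 98),
                          lut = perfusion_lut()) {
  metric <- match.arg(metric, PERFUSION_METRICS)
  sets <- Filter(Negate(is.null),
                 list(pre_maps$AP, pre_maps$LAT, post_maps$AP, post_maps$LAT))
  if (!length(sets)) .stopf("no map sets supplied")
  pool <- unlist(lapply(sets, function(s) s$maps[[metric]][s$validity_mask]))
  q <- stats::quantile(pool, probs = robust_pct / 100, names = FALSE, type = 7L)
  bounds <- c(q[1L], q[2L])
  d <- dim(sets[[1L]]$validity_mask)
  blank <- matrix(NaN, d[1L], d[2L])
  tile <- function(s) render_map(if (is.null(s)) blank else s$maps[[metric]],
                                 bounds, metric, lut)
  tl <- tile(pre_maps$AP); tr <- tile(pre_maps$LAT)
  br <- tile(post_maps$LAT); bl <- tile(post_maps$AP)
  H <- d[1L]; W <- d[2L]
  out <- array(0, c(2L * H, 2L * W, 3L))
  out[1:H, 1:W, ] <- tl
  out[1:H, W + 1:W, ] <- tr
  out[H + 1:H, W + 1:W, ] <- br
  out[H + 1:H, 1:W, ] <- bl
  # shared colorbar: full value sweep, hi at the top, lo at the bottom
  barw <- max(8L, round(W / 16))
  bar_u <- seq(1, 0, length.out = 2L * H)
  bar <- render_map(matrix(bar_u, 2L * H, 1L)[, rep(1L, barw), drop = FALSE],
                    c(0, 1), metric, lut)
  res <- array(0, c(2L * H, 2L * W + barw, 3L))
  res[, 1:(2L * W), ] <- out
  res[, 2L * W + 1:barw, ] <- bar
  attr(res, "meta") <- list(metric = metric, lo = unname(bounds[1L]),
                            hi = unname(bounds[2L]),
                            layout = "clockwise from top-left: pre-AP, pre-LAT, post-LAT, post-AP")
  res
}
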