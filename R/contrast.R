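#' Convert raw subtracted frames to a nonnegative contrast proxy
#'
#' The per-pixel baseline \eqn{b_{x,y}} is the mean of the first
#' `baseline_frames` frames. Under the standard DSA convention iodinated
#' contrast *darkens* the subtracted image, so `DARK_CONTRAST` takes
#' \eqn{C = \max(0, b - I)}; inverted exports use `BRIGHT_CONTRAST`,
#' \eqn{C = \max(0, I - b)}. The per-pixel baseline-window standard deviation
#' is retained for the downstream pixel-validity noise floor.
#'
#' @param seq a [frame_sequence()].
#' @param polarity `"DARK_CONTRAST"` (default) or `"BRIGHT_CONTRAST"`.
#' @param baseline_frames number of leading pre-injection frames
#'   (default 2; angiographic runs begin before the injection reaches the
#'   field of view).
#' @return a [contrast_sequence()].
#' @export
to_contrast <- function(seq, polarity = "DARK_CONTRAST", baseline_frames = 2L) {
  stopifnot(inherits(seq, "FrameSequence"))
  polarity <- match.arg(polarity, c("DARK_CONTRAST", "BRIGHT_CONTRAST"))
  nt <- dim(seq$frames)[3L]
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 1L || baseline_frames >= nt)
    .stopf("`baseline_frames` must be in [1, T-1]")
  bl <- seq$frames[, , seq_len(baseline_frames), drop = FALSE]
  b <- apply(bl, c(1L, 2L), mean)
  bsd <- if (baseline_frames >= 2L) apply(bl, c(1L, 2L), stats::sd)
         else matrix(0, dim(b)[1L], dim(b)[2L])
  C <- if (polarity == "DARK_CONTRAST") as.vector(b) - seq$frames
       else seq$frames - as.vector(b)
  C[C < 0] <- 0
  contrast_sequence(C, seq$times, baseline_frames, polarity,
                    baseline_sd = bsd, view = seq$view)
}

#' Detect the global signal-integration window
#'
#' Operates on the spatial-mean contrast curve \eqn{g(t)} (over the whole
#' frame or a supplied mask), matching the single global interval the method
#' uses: the window starts at the initiation of signal enhancement — the
#' first time \eqn{g} exceeds `enh_frac` of its peak — and ends at the arrest
#' of signal changes — the first post-peak time after which every
#' frame-to-frame change of \eqn{g} stays below `arrest_frac` of the peak —
#' or at the conclusion of the study, whichever occurs earlier.
#'
#' @param cs a [contrast_sequence()].
#' @param enh_frac enhancement-onset threshold, fraction of `max(g)`
#'   (default 0.05).
#' @param arrest_frac signal-arrest threshold on per-frame changes, fraction
#'   of `max(g)` (default 0.01).
#' @param mask optional logical `(H, W)` matrix restricting the spatial mean.
#' @return numeric `(t_start, t_end)` in seconds.
#' @export
detect_window <- function(cs, enh_frac = 0.05, arrest_frac = 0.01, mask = NULL) {
  stopifnot(inherits(cs, "ContrastSequence"))
  g <- if (is.null(mask)) apply(cs$contrast, 3L, mean)
       else apply(cs$contrast, 3L, function(f) mean(f[mask]))
  pk <- max(g)
  if (pk <= 0) .stopf("no enhancement detected: contrast stack is all zero")
  t <- cs$times
  i_start <- which(g > enh_frac * pk)[1L]
  i_pk <- which.max(g)
  nt <- length(g)
  i_end <- nt
  if (i_pk < nt) {
    dg <- abs(diff(g))                     # dg[k] = |g[k+1] - g[k]|, change into t[k+1]
    for (k in seq(i_pk + 1L, nt)) {
      if (all(dg[(k - 1L):(nt - 1L)] < arrest_frac * pk)) { i_end <- k; break }
    }
  }
  c(t_start = t[i_start], t_end = t[i_end])
}
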