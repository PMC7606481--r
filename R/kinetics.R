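#' @name bolus-kinetics
#' @title Single-curve bolus-tracking metrics
#'
#' @description
#' Deconvolution-free perfusion metrics of a contrast transit curve
#' \eqn{C(t)}, as used in DSA perfusion angiography:
#'
#' * **AT** — arrival time: the upward crossing of `at_frac` of the peak
#'   from which the curve rises to its maximum (contrast "first arrives").
#'   On a clean single-pass curve this is simply the first threshold
#'   crossing; under subtraction noise, taking the last up-crossing before
#'   the peak ignores isolated pre-arrival noise spikes that exceed the
#'   (deliberately low) threshold.
#' * **TTP** — time-to-peak: time of the global maximum sample, ties broken
#'   by the earliest occurrence.
#' * **TTD** — time-to-drain: last post-peak downward crossing of `ttd_frac`
#'   of the peak (contrast "has left").
#' * **MTT** — mean transit time, operationalized as the full width at half
#'   maximum: time between the first upward and last downward crossing of
#'   half the peak. This is the direct bolus-tracking definition, not the
#'   deconvolution MTT of CT/MR perfusion.
#' * **CBV** — relative blood volume: \eqn{\int C dt / \int C_{AIF} dt}
#'   (trapezoid rule on each curve's own grid, same window).
#' * **CBF** — blood flow by the central volume principle: CBV / MTT.
#'
#' All threshold crossings are located with sub-sample precision by linear
#' interpolation between the bracketing samples: DSA frame intervals
#' (0.25–1 s) are coarse relative to clinically relevant effect sizes
#' (0.3–1.6 s). Curves that have not returned below a threshold by the end
#' of the integration window are truncated there and flagged.
NULL

# first upward crossing of `th`, linearly interpolated; NA if never reached
.cross_up <- function(t, v, th) {
  if (v[1L] >= th) return(t[1L])
  n <- length(v)
  hit <- which(v[-1L] >= th & v[-n] < th)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L] + 1L
  t[i - 1L] + (th - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
}

# arrival crossing: the upward crossing of `th` from which the curve rises to
# its peak, i.e. the *last* up-crossing before the peak index. On a clean
# single-pass curve this equals the first crossing; under subtraction noise
# it ignores isolated pre-onset noise spikes above the (low) threshold.
.cross_arrival <- function(t, v, th, ipk) {
  below <- which(v[seq_len(ipk)] < th)
  if (!length(below)) return(t[1L])
  i <- below[length(below)]
  t[i] + (th - v[i]) / (v[i + 1L] - v[i]) * (t[i + 1L] - t[i])
}

# last downward crossing of `th` at or after index `from`; NA if none
.cross_down_last <- function(t, v, th, from = 1L) {
  n <- length(v)
  cand <- which(v[-n] >= th & v[-1L] < th)
  cand <- cand[cand >= from]
  if (!length(cand)) return(NA_real_)
  i <- cand[length(cand)]
  t[i] + (v[i] - th) / (v[i] - v[i + 1L]) * (t[i + 1L] - t[i])
}

.window_idx <- function(times, window) {
  if (is.null(window)) return(seq_along(times))
  which(times >= window[1L] - 1e-12 & times <= window[2L] + 1e-12)
}

#' @rdname bolus-kinetics
#' @param c a [time_intensity_curve()].
#' @param at_frac arrival threshold as a fraction of the peak (default 0.05).
#' @param window optional `(t_start, t_end)` integration window in seconds;
#'   metrics only see samples inside it.
#' @return `arrival_time()`: seconds, or `NA` for a flat-zero curve.
#' @export
arrival_time <- function(c, at_frac = 0.05, window = NULL) {
  i <- .window_idx(c$times, window)
  t <- c$times[i]; v <- c$values[i]
  pk <- max(v)
  if (pk <= 0) return(NA_real_)
  .cross_arrival(t, v, at_frac * pk, which.max(v))
}

#' @rdname bolus-kinetics
#' @return `time_to_peak()`: time of the earliest global-maximum sample.
#' @export
time_to_peak <- function(c, window = NULL) {
  i <- .window_idx(c$times, window)
  t <- c$times[i]; v <- c$values[i]
  if (max(v) <= 0) return(NA_real_)
  t[which.max(v)]
}

#' @rdname bolus-kinetics
#' @param ttd_frac drain threshold as a fraction of the peak (default 0.05).
#' @return `time_to_drain()`: seconds, with attribute `truncated = TRUE` when
#'   the curve never falls below the threshold inside the window (TTD is then
#'   the window end).
#' @export
time_to_drain <- function(c, ttd_frac = 0.05, window = NULL) {
  i <- .window_idx(c$times, window)
  t <- c$times[i]; v <- c$values[i]
  pk <- max(v)
  if (pk <= 0) return(NA_real_)
  ipk <- which.max(v)
  td <- .cross_down_last(t, v, ttd_frac * pk, from = ipk)
  if (is.na(td)) structure(t[length(t)], truncated = TRUE) else td
}

#' @rdname bolus-kinetics
#' @return `mean_transit_time()`: the FWHM in seconds, `truncated` attribute
#'   as for TTD when the curve ends above half maximum.
#' @export
mean_transit_time <- function(c, window = NULL) {
  i <- .window_idx(c$times, window)
  t <- c$times[i]; v <- c$values[i]
  pk <- max(v)
  if (pk <= 0) return(NA_real_)
  half <- pk / 2
  t_up <- .cross_up(t, v, half)
  ipk <- which.max(v)
  t_down <- .cross_down_last(t, v, half, from = ipk)
  if (is.na(t_down)) structure(t[length(t)] - t_up, truncated = TRUE)
  else t_down - t_up
}

#' @rdname bolus-kinetics
#' @param aif an [aif_curve()] (or any `TimeIntensityCurve`) providing
#'   \eqn{C_{AIF}(t)}.
#' @return `cbv()`: the dimensionless integral ratio.
#' @export
cbv <- function(c, aif, window = NULL) {
  ac <- if (inherits(aif, "AIFCurve")) aif$curve else aif
  ia <- .window_idx(ac$times, window)
  denom <- .trapz(ac$times[ia], ac$values[ia])
  if (denom <= 0) .stopf("AIF integral is zero: AIF line sees no contrast (misplaced?)")
  ic <- .window_idx(c$times, window)
  .trapz(c$times[ic], c$values[ic]) / denom
}

#' @rdname bolus-kinetics
#' @param cbv_val,mtt_val precomputed CBV (dimensionless) and MTT (seconds).
#' @return `cbf()`: flow in 1/seconds (central volume principle).
#' @export
cbf <- function(cbv_val, mtt_val) {
  if (!is.finite(mtt_val) || mtt_val <= 0) return(NA_real_)
  cbv_val / mtt_val
}

#' Default kinetics configuration
#'
#' @return list of tunable kinetics parameters: `at_frac`, `ttd_frac`
#'   (relative threshold crossings, default 5% of peak), `noise_floor_k`
#'   (pixel validity requires peak > `noise_floor_k` x baseline SD,
#'   default 3).
#' @export
kinetics_config <- function() {
  list(at_frac = 0.05, ttd_frac = 0.05, noise_floor_k = 3)
}

#' All six perfusion parameters of one curve
#'
#' Bundles AT, TTP, TTD, MTT, CBV and CBF. The result is valid only when the
#' curve peak exceeds the noise floor and the FWHM is positive; invalid
#' results carry `NaN` in every numeric field.
#'
#' @param c a [time_intensity_curve()].
#' @param aif the arterial input function curve.
#' @param window optional `(t_start, t_end)` integration window, seconds.
#' @param cfg configuration list, see [kinetics_config()].
#' @param noise_floor absolute validity threshold on the curve peak
#'   (contrast units); typically `noise_floor_k` times the pixel's
#'   baseline-window standard deviation.
#' @return a `PerfusionParams` list with fields `at_s`, `ttp_s`, `ttd_s`,
#'   `mtt_s`, `cbv`, `cbf`, `valid`, `truncated`.
#' @export
compute_params <- function(c, aif, window = NULL, cfg = kinetics_config(),
                           noise_floor = 0) {
  i <- .window_idx(c$times, window)
  pk <- max(c$values[i])
  invalid <- list(at_s = NaN, ttp_s = NaN, ttd_s = NaN, mtt_s = NaN,
                  cbv = NaN, cbf = NaN, valid = FALSE, truncated = FALSE)
  class(invalid) <- "PerfusionParams"
  if (pk <= 0 || pk <= noise_floor) return(invalid)
  at <- arrival_time(c, cfg$at_frac, window)
  ttp <- time_to_peak(c, window)
  ttd <- time_to_drain(c, cfg$ttd_frac, window)
  mtt <- mean_transit_time(c, window)
  trunc <- isTRUE(attr(ttd, "truncated")) || isTRUE(attr(mtt, "truncated"))
  if (!is.finite(mtt) || mtt <= 0) return(invalid)
  vol <- cbv(c, aif, window)
  out <- list(at_s = at, ttp_s = ttp, ttd_s = as.numeric(ttd),
              mtt_s = as.numeric(mtt), cbv = vol, cbf = cbf(vol, mtt),
              valid = TRUE, truncated = trunc)
  class(out) <- "PerfusionParams"
  out
}

# vectorized first-TRUE / last-TRUE column indices of a logical T x P matrix
.first_true <- function(B) {
  idx <- max.col(t(B), ties.method = "first")
  idx[!colSums(B)] <- NA_integer_
  idx
}
.last_true <- function(B) {
  idx <- max.col(t(B), ties.method = "last")
  idx[!colSums(B)] <- NA_integer_
  idx
}

# vectorized arrival crossing (last up-crossing before the column's peak)
.cross_arrival_mat <- function(t, V, th, ipk) {
  nT <- nrow(V); P <- ncol(V)
  B <- (V < rep(th, each = nT)) & (row(V) < rep(ipk, each = nT))
  i <- .last_true(B)
  out <- rep(t[1L], P)
  j <- which(!is.na(i))
  if (length(j)) {
    ii <- i[j]
    v1 <- V[cbind(ii, j)]; v2 <- V[cbind(ii + 1L, j)]
    out[j] <- t[ii] + (th[j] - v1) / (v2 - v1) * (t[ii + 1L] - t[ii])
  }
  out
}

# vectorized interpolated up-crossing over columns of V (T x P), thresholds th (P)
.cross_up_mat <- function(t, V, th) {
  P <- ncol(V)
  B <- V >= rep(th, each = nrow(V))
  i <- .first_true(B)
  out <- rep(NA_real_, P)
  at_first <- !is.na(i) & i == 1L
  out[at_first] <- t[1L]
  j <- which(!is.na(i) & i > 1L)
  if (length(j)) {
    ii <- i[j]
    v1 <- V[cbind(ii - 1L, j)]; v2 <- V[cbind(ii, j)]
    out[j] <- t[ii - 1L] + (th[j] - v1) / (v2 - v1) * (t[ii] - t[ii - 1L])
  }
  out
}

# vectorized interpolated last down-crossing at/after column-wise peak index
.cross_down_mat <- function(t, V, th, from) {
  nT <- nrow(V); P <- ncol(V)
  A <- V >= rep(th, each = nT)                 # above-threshold mask
  # candidate i: v[i] >= th & v[i+1] < th & i >= from
  C <- A[-nT, , drop = FALSE] & !A[-1L, , drop = FALSE]
  C <- C & (row(C) >= rep(from, each = nT - 1L))
  i <- .last_true(C)
  out <- rep(NA_real_, P)
  j <- which(!is.na(i))
  if (length(j)) {
    ii <- i[j]
    v1 <- V[cbind(ii, j)]; v2 <- V[cbind(ii + 1L, j)]
    out[j] <- t[ii] + (v1 - th[j]) / (v1 - v2) * (t[ii + 1L] - t[ii])
  }
  out
}

#' Voxel-wise perfusion maps of a contrast sequence
#'
#' Applies the single-curve metrics of [compute_params()] to every pixel with
#' vectorized matrix arithmetic. A pixel is valid when its contrast peak
#' (inside the window) exceeds `noise_floor_k` times its baseline-window
#' standard deviation and its FWHM is positive; all other pixels carry `NaN`
#' in every map. Pixels whose curve has not drained (or fallen below half
#' maximum) by the window end are truncated there and marked in the
#' `truncated` attribute map.
#'
#' @param cs a [contrast_sequence()].
#' @param aif the arterial input function ([aif_curve()]).
#' @param window optional `(t_start, t_end)` in seconds; default
#'   [detect_window()] output or the full time range.
#' @param cfg configuration, see [kinetics_config()].
#' @return a [perfusion_map_set()]; attribute `truncated` holds the logical
#'   truncation map.
#' @export
compute_maps <- function(cs, aif, window = NULL, cfg = kinetics_config()) {
  stopifnot(inherits(cs, "ContrastSequence"))
  d <- dim(cs$contrast)
  H <- d[1L]; W <- d[2L]
  if (is.null(window)) window <- c(cs$times[1L], cs$times[d[3L]])
  it <- .window_idx(cs$times, window)
  t <- cs$times[it]
  nT <- length(t)
  V <- matrix(aperm(cs$contrast[, , it, drop = FALSE], c(3L, 1L, 2L)), nrow = nT)

  pk <- do.call(pmax, lapply(seq_len(nT), function(k) V[k, ]))
  bsd <- if (is.null(cs$baseline_sd)) rep(0, H * W) else as.vector(cs$baseline_sd)
  candidate <- pk > 0 & pk > cfg$noise_floor_k * bsd

  Vc <- V[, candidate, drop = FALSE]
  pkc <- pk[candidate]
  P <- ncol(Vc)

  ipk <- .first_true(Vc == rep(pkc, each = nT))
  ttp <- t[ipk]
  at <- .cross_arrival_mat(t, Vc, cfg$at_frac * pkc, ipk)
  ttd <- .cross_down_mat(t, Vc, cfg$ttd_frac * pkc, ipk)
  ttd_trunc <- is.na(ttd)
  ttd[ttd_trunc] <- t[nT]
  half_up <- .cross_up_mat(t, Vc, pkc / 2)
  half_down <- .cross_down_mat(t, Vc, pkc / 2, ipk)
  mtt_trunc <- is.na(half_down)
  half_down[mtt_trunc] <- t[nT]
  mtt <- half_down - half_up

  ac <- if (inherits(aif, "AIFCurve")) aif$curve else aif
  ia <- .window_idx(ac$times, window)
  denom <- .trapz(ac$times[ia], ac$values[ia])
  if (denom <= 0) .stopf("AIF integral is zero: AIF line sees no contrast (misplaced?)")
  wts <- diff(t)
  wts <- c(wts / 2, 0) + c(0, wts / 2)     # trapezoid weights
  vol <- as.vector(wts %*% Vc) / denom

  ok <- is.finite(mtt) & mtt > 0 & is.finite(at)
  flow <- ifelse(ok, vol / mtt, NaN)

  blank <- function() matrix(NaN, H, W)
  maps <- list(at = blank(), ttp = blank(), ttd = blank(),
               mtt = blank(), cbv = blank(), cbf = blank())
  fill <- function(m, x) { m[candidate][ok] <- x[ok]; m }
  maps$at <- fill(maps$at, at)
  maps$ttp <- fill(maps$ttp, ttp)
  maps$ttd <- fill(maps$ttd, ttd)
  maps$mtt <- fill(maps$mtt, mtt)
  maps$cbv <- fill(maps$cbv, vol)
  maps$cbf <- fill(maps$cbf, flow)

  validity <- matrix(FALSE, H, W)
  validity[candidate][ok] <- TRUE
  truncated <- matrix(FALSE, H, W)
  truncated[candidate][ok] <- (ttd_trunc | mtt_trunc)[ok]

  ms <- perfusion_map_set(
    maps, validity, window, view = cs$view,
    meta = list(at_frac = cfg$at_frac, ttd_frac = cfg$ttd_frac,
                noise_floor_k = cfg$noise_floor_k,
                interpolation = "linear sub-sample crossings",
                mtt_convention = "FWHM of the contrast curve",
                window_rule = "global spatial-mean enhancement/arrest"))
  attr(ms, "truncated") <- truncated
  ms
}
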