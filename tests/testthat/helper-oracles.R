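# Independent brute-force oracles. These deliberately share no code with the
# package: curves are densified by linear resampling and every quantity is
# found by scanning sample indices on the dense grid, not by interpolation
# algebra.

gv_curve <- function(t, A, alpha, beta, t0) {
  tau <- t - t0
  out <- numeric(length(t))
  p <- tau > 0
  out[p] <- A * (tau[p] / (alpha * beta))^alpha * exp(alpha - tau[p] / beta)
  out
}

# brute-force metrics of a *sampled* curve: densify, then index-scan
bf_metrics <- function(times, values, at_frac = 0.05, ttd_frac = 0.05,
                       dt_dense = 1e-4) {
  td <- seq(times[1L], times[length(times)], by = dt_dense)
  vd <- stats::approx(times, values, xout = td)$y
  n <- length(vd)
  pk <- max(vd)
  ipk <- which.max(vd)
  # arrival: last below-threshold sample before the peak
  below <- which(vd[seq_len(ipk)] < at_frac * pk)
  at <- if (length(below)) td[below[length(below)] + 1L] else td[1L]
  # drain: last sample >= threshold at/after the peak
  above <- which(vd >= ttd_frac * pk)
  above <- above[above >= ipk]
  ttd <- td[above[length(above)]]
  # FWHM from half-max index extents
  up_half <- td[which(vd >= pk / 2)[1L]]
  ah <- which(vd >= pk / 2)
  down_half <- td[ah[length(ah)]]
  # integral: Riemann sum on the dense grid
  integral <- sum(vd) * dt_dense
  list(at = at, ttp = td[ipk], ttd = ttd, mtt = down_half - up_half,
       integral = integral)
}

# brute-force point-in-polygon (even-odd ray casting), one pixel at a time
bf_point_in_polygon <- function(r, cc, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    ri <- ring[i, 1L]; ci <- ring[i, 2L]
    rj <- ring[j, 1L]; cj <- ring[j, 2L]
    on_edge <- FALSE
    # boundary test: point on segment i-j
    d <- abs((cj - ci) * (r - ri) - (rj - ri) * (cc - ci))
    if (d < 1e-9 && cc >= min(ci, cj) - 1e-9 && cc <= max(ci, cj) + 1e-9 &&
        r >= min(ri, rj) - 1e-9 && r <= max(ri, rj) + 1e-9) return(TRUE)
    if ((ri > r) != (rj > r)) {
      x_int <- ci + (r - ri) / (rj - ri) * (cj - ci)
      if (cc < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

# small noise-free phantom for fast unit tests
tiny_phantom_spec <- function(noise_sd = 0, texture_amp = 0, seed = 11L,
                              H = 48L, W = 48L, T = 40L, dt = 0.25) {
  phantom_spec(
    H = H, W = W, T = T, dt = dt,
    territories = list(
      list(label = "MCA",
           polygon = rbind(c(18, 4), c(18, 22), c(44, 22), c(44, 4)),
           bolus = c(A = 30, alpha = 2, beta = 1.25, t0 = 2.2)),
      list(label = "ACA",
           polygon = rbind(c(18, 28), c(18, 44), c(44, 44), c(44, 28)),
           bolus = c(A = 30, alpha = 2, beta = 1.1, t0 = 2.4))),
    vessel = list(p0 = c(3, 24), p1 = c(12, 24), width_px = 3,
                  bolus = c(A = 60, alpha = 2, beta = 0.7, t0 = 1.6)),
    noise_sd = noise_sd, texture_amp = texture_amp, seed = seed)
}

# curve objects for the pinned analytic fixtures
fix_step_curve <- function() time_intensity_curve(0:5, c(0, 0, 4, 4, 4, 0))
fix_triangle_curve <- function() time_intensity_curve(0:8, c(0, 1, 2, 3, 4, 3, 2, 1, 0))
fix_boxcar_curve <- function(h = 4) time_intensity_curve(0:8, c(0, 0, h, h, h, h, h, 0, 0))
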