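test_that("threshold crossings interpolate between bracketing samples", {
  cv <- fix_step_curve()                       # [0,0,4,4,4,0] at t = 0..5
  expect_equal(arrival_time(cv, at_frac = 0.05), 1.05)
  expect_equal(as.numeric(time_to_drain(cv, ttd_frac = 0.05)), 4.95)
  # time shift moves AT by exactly the shift
  shifted <- time_intensity_curve(cv$times + 2, cv$values)
  expect_equal(arrival_time(shifted), 3.05)
})

test_that("MTT is the FWHM under the documented interpolation rule", {
  expect_identical(mean_transit_time(fix_triangle_curve()), 4)
  expect_identical(mean_transit_time(fix_boxcar_curve()), 5)
})

test_that("TTP is the earliest global maximum sample", {
  plateau <- time_intensity_curve(0:4, c(0, 5, 5, 5, 0))
  expect_equal(time_to_peak(plateau), 1)
  # finely sampled gamma-variate: analytic mode t0 + alpha*beta
  dt <- 0.05
  t <- seq(0, 20, by = dt)
  gcv <- time_intensity_curve(t, gamma_variate(t, 10, 2, 1.5, 3))
  expect_equal(time_to_peak(gcv), 6, tolerance = 0, ignore_attr = TRUE)
  expect_lte(abs(time_to_peak(gcv) - 6), dt / 2)
})

test_that("a monotonically rising curve truncates TTD and MTT at the window end", {
  rising <- time_intensity_curve(0:9, seq(0, 9))
  ttd <- time_to_drain(rising)
  expect_equal(as.numeric(ttd), 9)
  expect_true(attr(ttd, "truncated"))
  mtt <- mean_transit_time(rising)
  expect_true(attr(mtt, "truncated"))
})

test_that("CBV is an integral ratio with identity and linearity", {
  t <- seq(0, 20, by = 0.25)
  av <- gamma_variate(t, 40, 2, 1, 2)
  aif <- aif_curve(time_intensity_curve(t, av), rbind(c(1, 1), c(5, 5)), 5)
  expect_equal(cbv(aif$curve, aif), 1)
  half <- time_intensity_curve(t, av / 2)
  expect_equal(cbv(half, aif), 0.5)
  zero_aif <- time_intensity_curve(t, rep(0, length(t)))
  expect_error(cbv(half, zero_aif), "AIF integral is zero")
})

test_that("CBF follows the central volume principle", {
  expect_equal(cbf(0.5, 4), 0.125)
  expect_equal(cbf(0, 3), 0)
  expect_true(is.na(cbf(0.5, 0)))
})

test_that("metrics obey shift, amplitude and dilation laws", {
  t <- seq(0, 25, by = 0.25)
  cv <- time_intensity_curve(t, gamma_variate(t, 20, 2, 1.2, 3))
  av <- time_intensity_curve(t, gamma_variate(t, 50, 2, 0.8, 2))
  base <- list(at = arrival_time(cv), ttp = time_to_peak(cv),
               ttd = as.numeric(time_to_drain(cv)),
               mtt = as.numeric(mean_transit_time(cv)),
               cbv = cbv(cv, av))
  base$cbf <- cbf(base$cbv, base$mtt)

  # shift both curve and AIF by s: timings move by s, the rest is unchanged
  s <- 1.75
  cv_s <- time_intensity_curve(t + s, cv$values)
  av_s <- time_intensity_curve(t + s, av$values)
  expect_equal(arrival_time(cv_s), base$at + s)
  expect_equal(time_to_peak(cv_s), base$ttp + s)
  expect_equal(as.numeric(time_to_drain(cv_s)), base$ttd + s)
  expect_equal(as.numeric(mean_transit_time(cv_s)), base$mtt)
  expect_equal(cbv(cv_s, av_s), base$cbv)

  # joint amplitude scaling changes nothing; curve-only scaling hits CBV/CBF
  k <- 3.6
  cv_k <- time_intensity_curve(t, cv$values * k)
  av_k <- time_intensity_curve(t, av$values * k)
  expect_equal(arrival_time(cv_k), base$at)
  expect_equal(as.numeric(mean_transit_time(cv_k)), base$mtt)
  expect_equal(cbv(cv_k, av_k), base$cbv)
  expect_equal(cbv(cv_k, av), base$cbv * k)
  expect_equal(cbf(cbv(cv_k, av), as.numeric(mean_transit_time(cv_k))),
               base$cbf * k)

  # dilation t -> a t of the voxel curve (AIF fixed): timings and CBV scale
  # by a, CBF is unchanged
  a <- 1.8
  cv_a <- time_intensity_curve(t * a, cv$values)
  expect_equal(arrival_time(cv_a), base$at * a)
  expect_equal(time_to_peak(cv_a), base$ttp * a)
  expect_equal(as.numeric(time_to_drain(cv_a)), base$ttd * a)
  mtt_a <- as.numeric(mean_transit_time(cv_a))
  expect_equal(mtt_a, base$mtt * a)
  cbv_a <- cbv(cv_a, av)
  expect_equal(cbv_a, base$cbv * a)
  expect_equal(cbf(cbv_a, mtt_a), base$cbf, tolerance = 1e-6)
})

test_that("sampled metrics agree with the brute-force densified oracle", {
  set.seed(1)
  t <- seq(0, 40, by = 0.25)
  aifv <- gamma_variate(t, 50, 2, 0.8, 1)
  aif <- time_intensity_curve(t, aifv)
  aif_int <- bf_metrics(t, aifv)$integral
  for (i in 1:20) {
    al <- runif(1, 1, 4); be <- runif(1, 0.5, 3); t0 <- runif(1, 0, 5)
    cv <- time_intensity_curve(t, gamma_variate(t, 10, al, be, t0))
    bf <- bf_metrics(t, cv$values, dt_dense = 1e-3)
    expect_lt(abs(arrival_time(cv) - bf$at), 0.02)
    expect_lt(abs(time_to_peak(cv) - bf$ttp), 0.02)
    expect_lt(abs(as.numeric(time_to_drain(cv)) - bf$ttd), 0.02)
    expect_lt(abs(as.numeric(mean_transit_time(cv)) - bf$mtt), 0.02)
    expect_lt(abs(cbv(cv, aif) - bf$integral / aif_int) /
                (bf$integral / aif_int), 1e-3)
  }
})

test_that("vectorized maps match the scalar per-curve path pixel by pixel", {
  ph <- generate_phantom(tiny_phantom_spec(noise_sd = 1.5, texture_amp = 3))
  cs <- to_contrast(ph$sequence)
  aif <- extract_aif(cs, c(3, 24), c(12, 24))
  w <- detect_window(cs)
  maps <- compute_maps(cs, aif, w)
  idx <- which(maps$validity_mask, arr.ind = TRUE)
  set.seed(4)
  pick <- idx[sample(nrow(idx), 25), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    r <- pick[i, 1]; cc <- pick[i, 2]
    cv <- time_intensity_curve(cs$times, cs$contrast[r, cc, ])
    p <- compute_params(cv, aif, w,
                        noise_floor = 3 * cs$baseline_sd[r, cc])
    expect_true(p$valid)
    expect_equal(maps$maps$at[r, cc], p$at_s)
    expect_equal(maps$maps$ttp[r, cc], p$ttp_s)
    expect_equal(maps$maps$ttd[r, cc], p$ttd_s)
    expect_equal(maps$maps$mtt[r, cc], p$mtt_s)
    expect_equal(maps$maps$cbv[r, cc], p$cbv)
    expect_equal(maps$maps$cbf[r, cc], p$cbf)
  }
})

test_that("an all-zero stack maps to an all-invalid set", {
  cs <- contrast_sequence(array(0, c(8, 8, 6)), 0:5, 2L, "DARK_CONTRAST")
  aif <- time_intensity_curve(0:5, c(0, 1, 4, 2, 1, 0))
  maps <- compute_maps(cs, aif)
  expect_false(any(maps$validity_mask))
  expect_true(all(is.nan(maps$maps$at)))
})

test_that("AT <= TTP <= TTD on every valid pixel of random noisy phantoms", {
  for (seed in c(3L, 17L)) {
    ph <- generate_phantom(tiny_phantom_spec(noise_sd = 2, texture_amp = 5,
                                             seed = seed))
    cs <- to_contrast(ph$sequence)
    aif <- extract_aif(cs, c(3, 24), c(12, 24))
    maps <- compute_maps(cs, aif, detect_window(cs))
    v <- maps$validity_mask
    expect_gt(sum(v), 500)
    expect_true(all(maps$maps$at[v] <= maps$maps$ttp[v] + 1e-12))
    expect_true(all(maps$maps$ttp[v] <= maps$maps$ttd[v] + 1e-12))
    expect_true(all(maps$maps$mtt[v] > 0))
  }
})

test_that("an exact one-second-earlier bolus shifts AT/TTP and nothing else", {
  # fast kinetics so the transit is fully contained: the curve tail is below
  # double-precision noise at the window end
  mk <- function(t0s) {
    sp <- tiny_phantom_spec(noise_sd = 0, texture_amp = 0)
    sp$territories <- list(list(
      label = "MCA", polygon = rbind(c(18, 4), c(18, 22), c(44, 22), c(44, 4)),
      bolus = c(A = 30, alpha = 2, beta = 0.2, t0 = t0s)))
    sp$vessel$bolus <- c(A = 60, alpha = 2, beta = 0.2, t0 = t0s - 0.5)
    generate_phantom(sp)
  }
  pre <- mk(3.0); post <- mk(2.0)      # exactly 4 frames earlier
  run <- function(ph) {
    cs <- to_contrast(ph$sequence)
    compute_maps(cs, extract_aif(cs, c(3, 24), c(12, 24)))
  }
  m1 <- run(pre); m2 <- run(post)
  v <- m1$validity_mask & m2$validity_mask
  expect_gt(sum(v), 300)
  expect_equal(m2$maps$at[v], m1$maps$at[v] - 1)
  expect_equal(m2$maps$ttp[v], m1$maps$ttp[v] - 1)
  expect_lt(max(abs(m2$maps$mtt[v] - m1$maps$mtt[v])), 1e-9)
  expect_lt(max(abs(m2$maps$cbv[v] - m1$maps$cbv[v])), 1e-9)
})
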