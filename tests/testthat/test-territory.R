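# build a synthetic map set directly: every metric map given, full validity
make_maps <- function(mats, view = "AP") {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  base <- matrix(1, H, W)
  maps <- list(at = base, ttp = base * 2, ttd = base * 3, mtt = base * 2,
               cbv = base * 0.5, cbf = base * 0.25)
  maps[names(mats)] <- mats
  perfusion_map_set(maps, matrix(TRUE, H, W), c(0, 10), view = view)
}

test_that("a constant field summarizes to its value with zero spread", {
  ms <- make_maps(list(at = matrix(3, 10, 10)))
  roi <- roi_mask(matrix(TRUE, 10, 10), "MCA", "AP")
  s <- summarize_roi(ms, roi)
  at <- s[s$metric == "at", ]
  expect_equal(at$mean, 3)
  expect_equal(at$median, 3)
  expect_equal(at$sd, 0)
  expect_equal(at$skew, 0)
  expect_equal(at$kurtosis_excess, 0)
  expect_equal(at$n_valid_px, 100L)
})

test_that("two equal subregions summarize like the brute-force pixel list", {
  mtt <- matrix(2, 10, 10)
  mtt[, 6:10] <- 6
  ms <- make_maps(list(mtt = mtt))
  roi <- roi_mask(matrix(TRUE, 10, 10), "MCA", "AP")
  s <- summarize_roi(ms, roi)
  row <- s[s$metric == "mtt", ]
  x <- as.vector(mtt)                       # brute force over the pixel list
  expect_equal(row$mean, sum(x) / length(x))
  expect_equal(row$median, 4)
  expect_equal(row$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_equal(row$skew, 0)
})

test_that("pooled ROI mean is the pixel-count-weighted mean of sub-ROI means", {
  set.seed(8)
  at <- matrix(rnorm(100, 5), 10, 10)
  ms <- make_maps(list(at = at))
  left <- matrix(FALSE, 10, 10); left[, 1:4] <- TRUE
  right <- !left
  s_all <- summarize_roi(ms, roi_mask(matrix(TRUE, 10, 10)))
  s_l <- summarize_roi(ms, roi_mask(left))
  s_r <- summarize_roi(ms, roi_mask(right))
  g <- function(s) s[s$metric == "at", c("mean", "n_valid_px")]
  a <- g(s_all); l <- g(s_l); r <- g(s_r)
  expect_equal(a$mean,
               (l$mean * l$n_valid_px + r$mean * r$n_valid_px) /
                 (l$n_valid_px + r$n_valid_px))
})

test_that("an ROI with no valid pixels errors with its label", {
  m <- matrix(NaN, 6, 6)
  maps <- perfusion_map_set(list(at = m, ttp = m, ttd = m, mtt = m,
                                 cbv = m, cbf = m),
                            matrix(FALSE, 6, 6), c(0, 5))
  expect_error(summarize_roi(maps, roi_mask(matrix(TRUE, 6, 6), "PCA")),
               "PCA")
})

test_that("a constructed mean shift is recovered and called significant", {
  set.seed(12)
  pre_at <- matrix(rnorm(3600, mean = 5, sd = 0.4), 60, 60)
  post_at <- pre_at - 1.2
  pre <- make_maps(list(at = pre_at))
  post <- make_maps(list(at = post_at))
  roi <- roi_mask(matrix(TRUE, 60, 60), "MCA", "AP")
  cmp <- compare_pre_post(pre, post, roi)
  at <- cmp[cmp$metric == "at", ]
  expect_equal(at$delta_mean, -1.2)
  expect_true(at$significant)
  expect_lt(at$p_value, 1e-10)
  expect_gt(at$ci95_halfwidth, 0)
})

test_that("comparing a study with itself yields null deltas, p near 1", {
  set.seed(13)
  ms <- make_maps(list(at = matrix(rnorm(400, 4), 20, 20)))
  roi <- roi_mask(matrix(TRUE, 20, 20))
  cmp <- compare_pre_post(ms, ms, roi)
  expect_equal(cmp$delta_mean, rep(0, 6))
  expect_true(all(cmp$p_value > 0.99))
  expect_false(any(cmp$significant))
})

test_that("swapping pre and post negates every delta", {
  set.seed(14)
  a <- make_maps(list(at = matrix(rnorm(400, 4), 20, 20),
                      mtt = matrix(rnorm(400, 6), 20, 20)))
  b <- make_maps(list(at = matrix(rnorm(400, 3.4), 20, 20),
                      mtt = matrix(rnorm(400, 5.1), 20, 20)))
  roi <- roi_mask(matrix(TRUE, 20, 20))
  ab <- compare_pre_post(a, b, roi)
  ba <- compare_pre_post(b, a, roi)
  expect_equal(ba$delta_mean, -ab$delta_mean)
  expect_equal(ba$p_value, ab$p_value)
})

test_that("Welch p-values are uniform under the null", {
  set.seed(99)
  reps <- 200
  p <- replicate(reps, {
    stats::t.test(stats::rnorm(1e4), stats::rnorm(1e4),
                  var.equal = FALSE)$p.value
  })
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("across-case aggregation uses the t-based confidence interval", {
  mk <- function(d) {
    data.frame(roi = "MCA", view = "AP",
               metric = c("at", "ttp", "ttd", "mtt", "cbv", "cbf"),
               delta_mean = d, ci95_halfwidth = 0.1, p_value = 0.01,
               significant = TRUE, alpha = 0.05, n_pre = 100, n_post = 100)
  }
  cases <- list(mk(rep(-1, 6)), mk(rep(0, 6)), mk(rep(1, 6)))
  row <- aggregate_cases(cases)
  expect_equal(row$delta_at, 0)
  expect_equal(row$ci95_at, stats::qt(0.975, 2) * 1 / sqrt(3))
  expect_equal(row$n_cases, 3L)

  expect_warning(one <- aggregate_cases(cases[1]), "single case")
  expect_true(is.na(one$ci95_at))
  expect_equal(one$delta_ttp, -1)

  same <- aggregate_cases(list(mk(rep(0.5, 6)), mk(rep(0.5, 6))))
  expect_equal(same$ci95_mtt, 0)
  expect_equal(same$delta_mtt, 0.5)
})
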