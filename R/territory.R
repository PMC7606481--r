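#' Per-pixel metric values of a perfusion map inside an ROI
#'
#' @param maps a [perfusion_map_set()].
#' @param roi an [roi_mask()] on the same raster.
#' @return named list of numeric vectors, one per metric, valid in-ROI
#'   pixels only.
#' @export
roi_pixel_values <- function(maps, roi) {
  stopifnot(inherits(maps, "PerfusionMapSet"), inherits(roi, "ROIMask"))
  if (!identical(dim(roi$mask), dim(maps$validity_mask)))
    .stopf("ROI '%s' shape does not match the maps", roi$label)
  sel <- roi$mask & maps$validity_mask
  if (!any(sel)) .stopf("ROI '%s' contains no valid pixels", roi$label)
  lapply(maps$maps, function(m) m[sel])
}

.skew0 <- function(x) {
  if (length(x) < 3L || stats::sd(x) == 0) return(0)
  e1071::skewness(x, type = 2L)
}
.kurt0 <- function(x) {
  if (length(x) < 4L || stats::sd(x) == 0) return(0)
  e1071::kurtosis(x, type = 2L)
}

#' Distribution summary of perfusion metrics over a vascular territory
#'
#' For each of the six metrics, summarizes the distribution of valid in-ROI
#' pixel values: n, mean, median, sd, skew and kurtosis. Conventions (also
#' recorded in the output): sd uses the sample (n-1) denominator; skew and
#' kurtosis are the adjusted Fisher–Pearson estimators; kurtosis is *excess*
#' kurtosis (normal = 0); zero-variance distributions have skew and kurtosis
#' defined as 0.
#'
#' @param maps a [perfusion_map_set()].
#' @param roi an [roi_mask()].
#' @return data frame with one row per metric: `roi`, `view`, `metric`,
#'   `n_valid_px`, `mean`, `median`, `sd`, `skew`, `kurtosis_excess`.
#' @export
summarize_roi <- function(maps, roi) {
  vals <- roi_pixel_values(maps, roi)
  rows <- lapply(PERFUSION_METRICS, function(m) {
    x <- vals[[m]]
    data.frame(roi = roi$label, view = maps$view, metric = m,
               n_valid_px = length(x), mean = mean(x),
               median = stats::median(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               skew = .skew0(x), kurtosis_excess = .kurt0(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pre/post comparison of territory perfusion distributions
#'
#' Per metric: the change in means `delta_mean = post - pre`, a Welch
#' (unequal-variance, unpaired) two-sample test on the per-pixel
#' distributions, the 95% CI half-width from the Welch standard error, and a
#' significance call at `alpha`. Welch is used because pre and post pixel
#' sets are not in spatial correspondence (no registration); a paired test
#' on pixels is available for registered phantoms via `paired = TRUE`.
#'
#' Per-pixel samples within an ROI are spatially autocorrelated, so these
#' pixel-level p-values are anticonservative; `subsample_every` keeps every
#' k-th valid pixel as a crude effective-sample-size correction (default 1 =
#' off, matching the source methodology).
#'
#' @param pre_maps,post_maps [perfusion_map_set()] objects.
#' @param roi_pre,roi_post ROI masks for each study (often identical).
#' @param alpha significance level (default 0.05).
#' @param paired use a paired test on pixel-matched values.
#' @param subsample_every keep every k-th valid pixel (default 1).
#' @return a `TerritoryComparison` data frame: one row per metric with
#'   `delta_mean`, `ci95_halfwidth`, `p_value`, `significant`, plus `roi`,
#'   `view`, `alpha`, `n_pre`, `n_post`.
#' @export
compare_pre_post <- function(pre_maps, post_maps, roi_pre, roi_post = roi_pre,
                             alpha = 0.05, paired = FALSE,
                             subsample_every = 1L) {
  pre_v <- roi_pixel_values(pre_maps, roi_pre)
  post_v <- roi_pixel_values(post_maps, roi_post)
  keep <- function(x) x[seq(1L, length(x), by = subsample_every)]
  rows <- lapply(PERFUSION_METRICS, function(m) {
    a <- keep(pre_v[[m]]); b <- keep(post_v[[m]])
    dm <- mean(b) - mean(a)
    if (paired && length(a) == length(b)) {
      d <- b - a
      if (stats::sd(d) == 0) {
        p <- 1; hw <- 0
      } else {
        tt <- stats::t.test(d)
        p <- tt$p.value
        hw <- diff(tt$conf.int) / 2
      }
    } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p <- if (dm == 0) 1 else 0
      hw <- 0
    } else {
      tt <- stats::t.test(b, a, var.equal = FALSE)
      p <- tt$p.value
      hw <- diff(tt$conf.int) / 2
    }
    data.frame(roi = roi_pre$label, view = pre_maps$view, metric = m,
               delta_mean = dm, ci95_halfwidth = hw, p_value = p,
               significant = p < alpha, alpha = alpha,
               n_pre = length(a), n_post = length(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("TerritoryComparison", class(out))
  out
}

#' Aggregate per-case comparisons into a cohort table row
#'
#' Across cases (one `TerritoryComparison` per intervention), takes the mean
#' of `delta_mean` per metric with a t-based 95% confidence interval, in the
#' cohort-table layout: one row per (view, territory), columns
#' `delta_<metric>` and `ci95_<metric>` for the timing metrics AT, TTP, TTD,
#' MTT.
#'
#' @param comparisons list of `TerritoryComparison` data frames for the same
#'   territory and view.
#' @param roi_label,view row identity (defaults from the first comparison).
#' @return one-row data frame; with a single case the CI is undefined and
#'   emitted as `NA` with a warning.
#' @export
aggregate_cases <- function(comparisons, roi_label = NULL, view = NULL) {
  stopifnot(length(comparisons) >= 1L)
  roi_label <- roi_label %||% comparisons[[1L]]$roi[1L]
  view <- view %||% comparisons[[1L]]$view[1L]
  metrics <- c("at", "ttp", "ttd", "mtt")
  n <- length(comparisons)
  if (n == 1L) .warnf("single case: across-case 95%% CI is undefined")
  out <- data.frame(view = view, roi = roi_label, n_cases = n,
                    stringsAsFactors = FALSE)
  for (m in metrics) {
    d <- vapply(comparisons, function(cmp) cmp$delta_mean[cmp$metric == m],
                numeric(1))
    out[[paste0("delta_", m)]] <- mean(d)
    out[[paste0("ci95_", m)]] <-
      if (n > 1L) stats::qt(0.975, n - 1L) * stats::sd(d) / sqrt(n)
      else NA_real_
  }
  out
}
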