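#' Read a DSA frame sequence from disk
#'
#' Accepts a DICOM multi-frame file, a directory of single-frame DICOMs, or
#' a directory of ordered TIFF/PNG frames. DICOM frames are sorted by
#' InstanceNumber, image files lexicographically by filename. Frame times
#' come from DICOM FrameTimeVector/FrameTime when present, else from the
#' `times.json` sidecar written by [write_sequence()], else from
#' `times_override`, else default to uniform 1 s spacing with a warning —
#' never silently.
#'
#' @param path file or directory.
#' @param times_override optional numeric: either a full length-`T` vector of
#'   seconds, or a single frame interval `dt` in seconds.
#' @return a [frame_sequence()].
#' @export
read_sequence <- function(path, times_override = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE,
                             pattern = "\\.(dcm|DCM|tif|tiff|png|TIF|TIFF|PNG)$"))
    if (!length(files)) .stopf("%s: no DICOM/TIFF/PNG frames found", path)
    if (grepl("\\.dcm$", files[1L], ignore.case = TRUE)) {
      parts <- lapply(files, read_dicom)
      inst <- vapply(parts, function(p) p$instance_number %||% NA_real_, numeric(1))
      if (!anyNA(inst)) parts <- parts[order(inst)]
      shapes <- unique(lapply(parts, function(p) dim(p$frames)[1:2]))
      if (length(shapes) != 1L) .stopf("%s: heterogeneous frame shapes", path)
      frames <- array(unlist(lapply(parts, function(p) p$frames)),
                      c(shapes[[1L]], length(parts)))
      times <- NULL
      view <- parts[[1L]]$view
      spacing <- parts[[1L]]$pixel_spacing_mm
    } else {
      mats <- lapply(files, .read_gray)
      shapes <- unique(lapply(mats, dim))
      if (length(shapes) != 1L) .stopf("%s: heterogeneous frame shapes", path)
      frames <- array(unlist(mats), c(shapes[[1L]], length(mats)))
      times <- NULL
      view <- NULL
      spacing <- NULL
      sidecar <- file.path(path, "times.json")
      if (file.exists(sidecar)) {
        sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        times <- sc$times
        view <- sc$view
        spacing <- sc$pixel_spacing_mm
        if (!is.null(sc$scale))
          frames <- sc$scale[1L] + frames * (sc$scale[2L] - sc$scale[1L])
      }
    }
  } else {
    x <- read_dicom(path)
    frames <- x$frames
    times <- x$times
    view <- x$view
    spacing <- x$pixel_spacing_mm
  }
  nt <- dim(frames)[3L]
  if (is.null(times)) {
    if (!is.null(times_override)) {
      times <- if (length(times_override) == 1L)
        (seq_len(nt) - 1L) * times_override else times_override
    } else {
      .warnf("%s: no frame timing found; assuming uniform 1 s spacing", path)
      times <- seq_len(nt) - 1
    }
  }
  view <- .normalize_view(view)
  frame_sequence(frames, times, view = view, pixel_spacing_mm = spacing,
                 source_id = path)
}

.normalize_view <- function(view) {
  if (is.null(view) || !nzchar(view)) return("UNKNOWN")
  v <- toupper(view)
  if (v == "AP") "AP"
  else if (v %in% c("LAT", "LL", "RL", "LATERAL")) "LAT"
  else "UNKNOWN"
}

.read_gray <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
         else tiff::readTIFF(f)
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)  # flatten RGB
  img
}

#' Write a frame sequence as a float TIFF stack with a timing sidecar
#'
#' One 32-bit float TIFF per frame (`f0000.tif`, ...) plus `times.json`
#' holding times, view, pixel spacing and the intensity scale. Samples are
#' range-scaled into `[0, 1]` for storage and rescaled on read; round-trips
#' are value-identical within float32 precision.
#'
#' @param seq a [frame_sequence()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sequence <- function(seq, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(seq$frames)
  if (rng[2L] <= rng[1L]) rng <- rng + c(0, 1)
  nt <- dim(seq$frames)[3L]
  for (k in seq_len(nt)) {
    m <- (seq$frames[, , k] - rng[1L]) / (rng[2L] - rng[1L])
    tiff::writeTIFF(m, file.path(out_dir, sprintf("f%04d.tif", k - 1L)),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  jsonlite::write_json(
    list(times = seq$times, view = seq$view,
         pixel_spacing_mm = seq$pixel_spacing_mm, scale = rng,
         source_id = seq$source_id),
    file.path(out_dir, "times.json"),
    auto_unbox = FALSE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Build an ROI mask from a raster file or polygon specification
#'
#' Two spec forms are accepted: a raster PNG (any nonzero pixel is in-ROI),
#' or a polygon JSON dialect
#' `{"label": ..., "view": ..., "rings": [[[r, c], ...], ...]}` with closed
#' 1-based pixel-coordinate rings. Polygons are rasterized with the even-odd
#' rule: a pixel is in-ROI when its center lies inside (boundary centers
#' included).
#'
#' @param spec path to a `.png` raster or `.json` polygon file, or an
#'   already-parsed list in the polygon dialect.
#' @param shape target `(H, W)`; required for polygon specs, checked for
#'   rasters.
#' @param label,view overrides for the mask metadata.
#' @return an [roi_mask()].
#' @export
read_mask <- function(spec, shape = NULL, label = NULL, view = NULL) {
  if (is.character(spec) && grepl("\\.png$", spec, ignore.case = TRUE)) {
    img <- png::readPNG(spec)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (!is.null(shape) && !identical(dim(img), as.integer(shape)))
      .stopf("mask raster is %dx%d, expected %dx%d",
             nrow(img), ncol(img), shape[1L], shape[2L])
    mask <- img != 0
  } else {
    pj <- if (is.character(spec)) jsonlite::read_json(spec, simplifyVector = TRUE)
          else spec
    if (is.null(shape)) .stopf("polygon masks need a target `shape`")
    label <- label %||% pj$label
    view <- view %||% pj$view
    mask <- rasterize_polygon(pj$rings, shape)
  }
  if (!any(mask)) .stopf("mask rasterization is empty")
  roi_mask(mask, label = label %||% "CUSTOM", view = view %||% "UNKNOWN")
}

#' Rasterize polygon rings with the even-odd rule
#'
#' @param rings a list of closed rings; each ring is an `n x 2` matrix (or
#'   list of pairs) of 1-based `(row, col)` vertices.
#' @param shape `(H, W)` raster shape.
#' @return logical matrix; pixel centers inside an odd number of rings are
#'   `TRUE` (boundary included).
#' @export
rasterize_polygon <- function(rings, shape) {
  # normalize to a list of n x 2 matrices, whatever the JSON simplifier made
  if (is.array(rings) && length(dim(rings)) == 3L) {
    rings <- lapply(seq_len(dim(rings)[1L]), function(i) rings[i, , ])
  } else if (is.matrix(rings)) {
    rings <- list(rings)
  } else if (is.list(rings)) {
    is_pair <- function(x) is.numeric(unlist(x)) && length(unlist(x)) == 2L
    if (all(vapply(rings, is_pair, logical(1))))
      rings <- list(do.call(rbind, lapply(rings, unlist)))
    else
      rings <- lapply(rings, function(r)
        if (is.matrix(r)) r else do.call(rbind, lapply(r, unlist)))
  } else .stopf("cannot interpret polygon rings")
  H <- shape[1L]; W <- shape[2L]
  mask <- matrix(FALSE, H, W)
  grid_r <- rep(seq_len(H), times = W)
  grid_c <- rep(seq_len(W), each = H)
  for (rg in rings) {
    if (nrow(rg) < 3L) .stopf("polygon ring needs at least 3 vertices")
    r <- rg[, 1L]; cc <- rg[, 2L]
    area <- abs(sum(r * c(cc[-1L], cc[1L]) - c(r[-1L], r[1L]) * cc)) / 2
    if (area <= 0) .stopf("degenerate polygon ring with zero area")
    if (any(rg[, 1L] < 0.5 | rg[, 1L] > H + 0.5 | rg[, 2L] < 0.5 | rg[, 2L] > W + 0.5))
      .stopf("polygon ring extends outside the %dx%d frame", H, W)
    inside <- pracma::inpolygon(grid_c, grid_r, rg[, 2L], rg[, 1L],
                                boundary = TRUE)
    mask <- xor(mask, matrix(inside, H, W))   # even-odd composition of rings
  }
  if (!any(mask)) .stopf("polygon rasterizes to zero pixels")
  mask
}

#' Write a perfusion map set to disk
#'
#' One 32-bit float TIFF per metric (range-scaled to `[0, 1]`, with the
#' affine bounds recorded in `maps.json`), the validity mask as a PNG and a
#' JSON metadata file (integration window, view, per-map scale,
#' computation conventions).
#'
#' @param maps a [perfusion_map_set()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_maps <- function(maps, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scales <- list()
  for (m in PERFUSION_METRICS) {
    x <- maps$maps[[m]]
    fin <- x[is.finite(x)]
    rng <- if (length(fin)) range(fin) else c(0, 1)
    if (rng[2L] <= rng[1L]) rng[2L] <- rng[1L] + 1
    y <- (x - rng[1L]) / (rng[2L] - rng[1L])
    y[!is.finite(y)] <- 0
    tiff::writeTIFF(y, file.path(out_dir, paste0(m, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
    scales[[m]] <- rng
  }
  png::writePNG(maps$validity_mask * 1, file.path(out_dir, "validity.png"))
  jsonlite::write_json(
    list(times_window = maps$times_window, view = maps$view,
         scale = scales, meta = maps$meta),
    file.path(out_dir, "maps.json"), auto_unbox = FALSE, digits = NA,
    null = "null")
  invisible(out_dir)
}

#' Read back a perfusion map set written by [write_maps()]
#'
#' @param in_dir directory produced by [write_maps()].
#' @return a [perfusion_map_set()].
#' @export
read_maps <- function(in_dir) {
  meta <- jsonlite::read_json(file.path(in_dir, "maps.json"),
                              simplifyVector = TRUE)
  mask <- png::readPNG(file.path(in_dir, "validity.png")) != 0
  if (length(dim(mask)) == 3L) mask <- mask[, , 1L]
  out <- list()
  for (m in PERFUSION_METRICS) {
    y <- tiff::readTIFF(file.path(in_dir, paste0(m, ".tif")))
    rng <- meta$scale[[m]]
    x <- rng[1L] + y * (rng[2L] - rng[1L])
    x[!mask] <- NaN
    out[[m]] <- x
  }
  perfusion_map_set(out, mask, meta$times_window,
                    view = meta$view %||% "UNKNOWN",
                    meta = as.list(meta$meta))
}

#' Write territory summary and comparison tables
#'
#' `summaries.csv` has one row per (roi, view, metric) with the distribution
#' features (n, mean, median, sd, skew, excess kurtosis); `comparison.csv`
#' mirrors the pre/post comparison layout with one row per (roi, view,
#' metric): `delta_mean` (post - pre), `ci95_halfwidth`, `p_value`,
#' `significant`.
#'
#' @param summaries data frame from [summarize_roi()] (rows may be bound
#'   across ROIs/views), or `NULL`.
#' @param comparisons data frame from [compare_pre_post()], or `NULL`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_tables <- function(summaries, comparisons, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(summaries))
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
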