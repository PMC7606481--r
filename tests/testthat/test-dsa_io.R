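test_that("a PNG frame directory reads with override or default timing", {
  d <- withr::local_tempdir()
  set.seed(2)
  for (k in 0:11) {
    png::writePNG(matrix(runif(64), 8, 8), file.path(d, sprintf("f%02d.png", k)))
  }
  seqn <- read_sequence(d, times_override = 0.5)
  expect_equal(seqn$times, (0:11) * 0.5)
  expect_equal(dim(seqn$frames), c(8L, 8L, 12L))
  expect_warning(s2 <- read_sequence(d), "assuming uniform 1 s")
  expect_equal(s2$times, 0:11)
})

test_that("a written sequence re-reads value-identical within float32", {
  ph <- generate_phantom(tiny_phantom_spec(noise_sd = 2, texture_amp = 5))
  d <- withr::local_tempdir()
  write_sequence(ph$sequence, d)
  back <- read_sequence(d)
  rng <- diff(range(ph$sequence$frames))
  expect_lt(max(abs(back$frames - ph$sequence$frames)), 1e-6 * rng)
  expect_lt(max(abs(back$times - ph$sequence$times)), 1e-9)
  expect_equal(back$view, ph$sequence$view)
})

test_that("DICOM multi-frame round-trips frames and FrameTimeVector timing", {
  set.seed(5)
  fr <- array(sample(0:4095, 10 * 12 * 6, TRUE), c(10, 12, 6))
  times <- cumsum(c(0, rep(0.1, 5)))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(fr, f, times = times, view = "LAT", pixel_spacing_mm = c(0.2, 0.2))
  seqn <- read_sequence(f)
  expect_identical(seqn$frames, fr * 1.0)       # bit-identical integers
  expect_equal(seqn$times, times, tolerance = 1e-9)  # [0,100,100,...] ms cumulated
  expect_equal(seqn$view, "LAT")
  expect_equal(seqn$pixel_spacing_mm, c(0.2, 0.2))
})

test_that("a directory of single-frame DICOMs sorts by InstanceNumber", {
  d <- withr::local_tempdir()
  fr <- array(0L, c(4, 4, 3))
  for (k in 1:3) fr[, , k] <- k * 100L
  # filenames deliberately disagree with acquisition order
  write_dicom(fr[, , 2], file.path(d, "a.dcm"), instance_number = 2)
  write_dicom(fr[, , 3], file.path(d, "b.dcm"), instance_number = 3)
  write_dicom(fr[, , 1], file.path(d, "c.dcm"), instance_number = 1)
  seqn <- read_sequence(d, times_override = 0.25)
  expect_equal(seqn$frames[1, 1, ], c(100, 200, 300))
})

test_that("MONOCHROME1 pixel values are inverted on read", {
  f <- withr::local_tempfile(fileext = ".dcm")
  fr <- matrix(c(0L, 100L, 65535L, 40000L), 2, 2)
  write_dicom(array(fr, c(2, 2, 1)), f, photometric = "MONOCHROME1")
  x <- read_dicom(f)
  expect_equal(x$frames[, , 1], 65535 - fr)
})

test_that("our DICOM encoding agrees with pydicom both ways", {
  py <- Sys.which("python")
  stopifnot(nzchar(py))
  set.seed(9)
  fr <- array(sample(0:1000, 6 * 5 * 3, TRUE), c(6, 5, 3))
  f1 <- withr::local_tempfile(fileext = ".dcm")
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(fr, f1, times = c(0, 0.2, 0.4), view = "AP")
  script <- sprintf("
import pydicom, sys
ds = pydicom.dcmread(%s)
arr = ds.pixel_array
print(int(arr.sum()), arr.shape[0], ds.Rows, ds.Columns, ds.ViewPosition)
ds.save_as(%s, enforce_file_format=True)
", deparse(f1), deparse(f2))
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2(py, sf, stdout = TRUE)
  parts <- strsplit(trimws(out), " ")[[1]]
  expect_equal(as.numeric(parts[1]), sum(fr))   # pydicom sees our pixels
  expect_equal(as.integer(parts[2:4]), c(3L, 6L, 5L))
  expect_equal(parts[5], "AP")
  back <- read_dicom(f2)                        # we read pydicom's rewrite
  expect_identical(back$frames, fr * 1.0)
  expect_equal(back$times, c(0, 0.2, 0.4))
})

test_that("polygon masks rasterize by the center-inclusive even-odd rule", {
  ring <- rbind(c(10, 10), c(10, 30), c(20, 30), c(20, 10))
  m <- rasterize_polygon(ring, c(64, 64))
  expect_equal(sum(m), 11L * 21L)               # 231 px, boundary included
  # brute-force point-in-polygon oracle over every pixel center
  for (r in c(9, 10, 15, 20, 21)) for (cc in c(9, 10, 22, 30, 31)) {
    expect_identical(m[r, cc], bf_point_in_polygon(r, cc, ring),
                     label = sprintf("pixel (%d,%d)", r, cc))
  }
  # ring with a hole: even-odd composition
  hole <- rbind(c(13, 14), c(13, 20), c(17, 20), c(17, 14))
  m2 <- rasterize_polygon(list(ring, hole), c(64, 64))
  expect_lt(sum(m2), sum(m))
  expect_false(m2[15, 17])
  expect_true(m2[11, 12])
})

test_that("degenerate polygons and empty masks are rejected", {
  expect_error(rasterize_polygon(rbind(c(5, 5), c(5, 9), c(5, 5)), c(32, 32)),
               "zero area")
  expect_error(read_mask(list(label = "CUSTOM", view = "AP",
                              rings = rbind(c(2, 2), c(2, 4), c(2, 2))),
                         shape = c(16, 16)),
               "zero area")
})

test_that("mask specs read from raster PNG and polygon JSON", {
  d <- withr::local_tempdir()
  png::writePNG(matrix(1, 16, 16), file.path(d, "all.png"))
  m <- read_mask(file.path(d, "all.png"), shape = c(16, 16), label = "MCA")
  expect_equal(sum(m$mask), 256L)
  expect_equal(m$label, "MCA")

  pj <- file.path(d, "roi.json")
  jsonlite::write_json(
    list(label = "ACA", view = "AP",
         rings = list(list(c(2, 2), c(2, 6), c(6, 6), c(6, 2)))),
    pj, auto_unbox = TRUE)
  m2 <- read_mask(pj, shape = c(16, 16))
  expect_equal(sum(m2$mask), 25L)
  expect_equal(m2$label, "ACA")
  expect_equal(m2$view, "AP")
})

test_that("perfusion maps round-trip through TIFF/PNG/JSON", {
  ph <- generate_phantom(tiny_phantom_spec(noise_sd = 1, texture_amp = 3))
  cs <- to_contrast(ph$sequence)
  maps <- compute_maps(cs, extract_aif(cs, c(3, 24), c(12, 24)),
                       detect_window(cs))
  d <- withr::local_tempdir()
  write_maps(maps, d)
  back <- read_maps(d)
  expect_identical(back$validity_mask, maps$validity_mask)
  for (m in PERFUSION_METRICS) {
    a <- maps$maps[[m]]; b <- back$maps[[m]]
    expect_identical(is.nan(a), is.nan(b))
    rng <- diff(range(a[is.finite(a)]))
    expect_lt(max(abs(a[is.finite(a)] - b[is.finite(b)])), 1e-6 * max(rng, 1))
  }
  expect_equal(back$times_window, maps$times_window)
})

test_that("summary and comparison tables write the expected CSV schema", {
  ph <- generate_phantom(tiny_phantom_spec(noise_sd = 1, texture_amp = 3))
  cs <- to_contrast(ph$sequence)
  maps <- compute_maps(cs, extract_aif(cs, c(3, 24), c(12, 24)),
                       detect_window(cs))
  roi <- roi_mask(rasterize_polygon(rbind(c(18, 4), c(18, 22), c(44, 22), c(44, 4)),
                                    c(48, 48)), "MCA", "AP")
  s <- summarize_roi(maps, roi)
  cmp <- compare_pre_post(maps, maps, roi)
  d <- withr::local_tempdir()
  write_tables(s, cmp, d)
  s2 <- utils::read.csv(file.path(d, "summaries.csv"))
  expect_setequal(names(s2), c("roi", "view", "metric", "n_valid_px", "mean",
                               "median", "sd", "skew", "kurtosis_excess"))
  c2 <- utils::read.csv(file.path(d, "comparison.csv"))
  expect_true(all(c("roi", "view", "metric", "delta_mean", "ci95_halfwidth",
                    "p_value", "significant") %in% names(c2)))
  expect_equal(nrow(c2), 6L)                     # one row per metric
})
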