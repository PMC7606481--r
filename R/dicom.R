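# Minimal DICOM support: uncompressed monochrome little-endian files only
# (explicit VR on write; explicit or implicit VR on read). Covers the tags a
# DSA cine pipeline needs -- geometry, frame timing, view, instance order,
# photometric interpretation, pixel data. Compressed transfer syntaxes,
# sequences of undefined length and big-endian files are out of scope.

.DICOM_EXPLICIT <- "1.2.840.10008.1.2.1"
.DICOM_IMPLICIT <- "1.2.840.10008.1.2"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.dcm_pad <- function(raw_val, pad = as.raw(0x20)) {
  if (length(raw_val) %% 2L == 1L) c(raw_val, pad) else raw_val
}

# one explicit-VR little-endian element
.dcm_element <- function(group, elem, vr, value) {
  val <- switch(vr,
    US = .u16(value),
    UL = .u32(value),
    OW = value,                                   # already raw
    OB = value,
    UI = .dcm_pad(charToRaw(paste(value, collapse = "\\")), as.raw(0x00)),
    .dcm_pad(charToRaw(paste(value, collapse = "\\"))))   # DS/IS/CS/LO/SH/PN
  hdr <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), .u32(length(val)), val)
  } else {
    c(hdr, .u16(length(val)), val)
  }
}

#' Write a frame stack as a DICOM multi-frame file
#'
#' Explicit-VR little-endian secondary-capture object with 16-bit unsigned
#' MONOCHROME2 pixels. Frame timing is stored as a FrameTimeVector
#' (milliseconds, increments); the projection view goes to ViewPosition.
#' Intensities must already be integers in `[0, 65535]`.
#'
#' @param frames numeric `(H, W, T)` array of integer-valued intensities.
#' @param path output file.
#' @param times optional frame midpoint times (seconds) of length `T`.
#' @param view optional `"AP"`/`"LAT"` view code.
#' @param pixel_spacing_mm optional (row, col) spacing.
#' @param instance_number optional integer instance number.
#' @param photometric `"MONOCHROME2"` (default) or `"MONOCHROME1"`.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(frames, path, times = NULL, view = NULL,
                        pixel_spacing_mm = NULL, instance_number = NULL,
                        photometric = "MONOCHROME2") {
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  d <- dim(frames)
  v <- as.vector(frames)
  if (any(v != round(v)) || min(v) < 0 || max(v) > 65535)
    .stopf("DICOM writer needs integer intensities in [0, 65535]")
  photometric <- match.arg(photometric, c("MONOCHROME2", "MONOCHROME1"))

  sop_class <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture
  sop_inst <- paste0("1.2.826.0.1.3680043.8.498.",
                     paste(sample.int(9, 8, replace = TRUE), collapse = ""))

  meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcm_element(0x0002, 0x0002, "UI", sop_class),
    .dcm_element(0x0002, 0x0003, "UI", sop_inst),
    .dcm_element(0x0002, 0x0010, "UI", .DICOM_EXPLICIT))
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)

  # pixel bytes: frames are (H, W, T); DICOM stores each frame row-major
  px <- unlist(lapply(seq_len(d[3L]), function(k)
    writeBin(as.integer(t(frames[, , k])), raw(), size = 2L, endian = "little")))

  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  ds <- c(
    .dcm_element(0x0008, 0x0016, "UI", sop_class),
    .dcm_element(0x0008, 0x0018, "UI", sop_inst))
  if (!is.null(times)) {
    if (length(times) != d[3L]) .stopf("length(times) must equal frame count")
    ftv_ms <- c(0, diff(times)) * 1000
    ds <- c(ds, .dcm_element(0x0018, 0x1065, "DS", fmt(ftv_ms)))
  }
  if (!is.null(view))
    ds <- c(ds, .dcm_element(0x0018, 0x5101, "CS", view))
  if (!is.null(instance_number))
    ds <- c(ds, .dcm_element(0x0020, 0x0013, "IS", as.character(instance_number)))
  ds <- c(ds,
    .dcm_element(0x0028, 0x0002, "US", 1L),
    .dcm_element(0x0028, 0x0004, "CS", photometric))
  if (d[3L] > 1L)
    ds <- c(ds, .dcm_element(0x0028, 0x0008, "IS", as.character(d[3L])))
  ds <- c(ds,
    .dcm_element(0x0028, 0x0010, "US", d[1L]),
    .dcm_element(0x0028, 0x0011, "US", d[2L]))
  if (!is.null(pixel_spacing_mm))
    ds <- c(ds, .dcm_element(0x0028, 0x0030, "DS", fmt(pixel_spacing_mm)))
  ds <- c(ds,
    .dcm_element(0x0028, 0x0100, "US", 16L),
    .dcm_element(0x0028, 0x0101, "US", 16L),
    .dcm_element(0x0028, 0x0102, "US", 15L),
    .dcm_element(0x0028, 0x0103, "US", 0L),
    .dcm_element(0x7FE0, 0x0010, "OW", px))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

.raw_to_str <- function(r) trimws(rawToChar(r[r != as.raw(0)]))

.read_u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
.read_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

# parse top-level data set elements from `off` (0-based); returns named list
.dcm_parse <- function(bytes, off, explicit) {
  n <- length(bytes)
  out <- list()
  while (off + 8L <= n) {
    group <- .read_u16(bytes, off)
    elem <- .read_u16(bytes, off + 2L)
    key <- sprintf("%04X,%04X", group, elem)
    if (explicit && group != 0xFFFE) {
      vr <- rawToChar(bytes[off + 5:6])
      if (vr %in% .LONG_VRS) {
        len <- .read_u32(bytes, off + 8L); hdr <- 12L
      } else {
        len <- .read_u16(bytes, off + 6L); hdr <- 8L
      }
    } else {
      vr <- "UN"
      len <- .read_u32(bytes, off + 4L); hdr <- 8L
    }
    if (len == 4294967295) .stopf("undefined-length DICOM element %s unsupported", key)
    val_off <- off + hdr
    out[[key]] <- list(vr = vr, off = val_off, len = len)
    off <- val_off + len
  }
  out
}

.dcm_str <- function(bytes, el) {
  if (is.null(el) || el$len == 0L) return(NULL)
  .raw_to_str(bytes[el$off + seq_len(el$len)])
}
.dcm_num <- function(bytes, el) {
  s <- .dcm_str(bytes, el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1L]])
}
.dcm_us <- function(bytes, el) {
  if (is.null(el)) return(NULL)
  .read_u16(bytes, el$off)
}

#' Read one DICOM file (single- or multi-frame)
#'
#' Supports uncompressed explicit- and implicit-VR little-endian transfer
#' syntaxes. MONOCHROME1 images are inverted on read so that higher stored
#' values always mean brighter pixels.
#'
#' @param path DICOM file path.
#' @return list with `frames` (`(H, W, T)` double array), `times` (seconds,
#'   or `NULL` when the file carries no frame timing), `view`,
#'   `pixel_spacing_mm`, `instance_number`.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  n <- length(bytes)
  off <- 0L
  ts <- NULL
  if (n > 132L && rawToChar(bytes[129:132]) == "DICM") {
    off <- 132L
    # walk the file meta group (always explicit VR) while group == 0x0002
    while (off + 8L <= n && .read_u16(bytes, off) == 2L) {
      elem <- .read_u16(bytes, off + 2L)
      vr <- rawToChar(bytes[off + 5:6])
      if (vr %in% .LONG_VRS) {
        len <- .read_u32(bytes, off + 8L); hdr <- 12L
      } else {
        len <- .read_u16(bytes, off + 6L); hdr <- 8L
      }
      if (elem == 0x0010)
        ts <- .raw_to_str(bytes[off + hdr + seq_len(len)])
      off <- off + hdr + len
    }
  }
  explicit <- if (identical(ts, .DICOM_IMPLICIT)) FALSE
              else if (is.null(ts) || identical(ts, .DICOM_EXPLICIT)) TRUE
              else .stopf("%s: unsupported transfer syntax %s", path, ts)
  if (is.null(ts)) {
    # headerless file: sniff the VR bytes of the first element
    explicit <- rawToChar(bytes[off + 5:6]) %in%
      c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT","OB","OF",
        "OW","PN","SH","SL","SQ","SS","ST","TM","UI","UL","UN","US","UT")
  }
  els <- .dcm_parse(bytes, off, explicit)

  rows <- .dcm_us(bytes, els[["0028,0010"]])
  cols <- .dcm_us(bytes, els[["0028,0011"]])
  if (is.null(rows) || is.null(cols)) .stopf("%s: no image geometry", path)
  bits <- .dcm_us(bytes, els[["0028,0100"]]) %||% 16L
  nfr <- .dcm_num(bytes, els[["0028,0008"]]) %||% 1
  nfr <- as.integer(nfr)
  photometric <- .dcm_str(bytes, els[["0028,0004"]]) %||% "MONOCHROME2"

  px <- els[["7FE0,0010"]]
  if (is.null(px)) .stopf("%s: no pixel data", path)
  npx <- rows * cols * nfr
  if (bits == 16L) {
    v <- readBin(bytes[px$off + seq_len(2L * npx)], integer(), n = npx,
                 size = 2L, signed = FALSE, endian = "little")
  } else if (bits == 8L) {
    v <- as.integer(bytes[px$off + seq_len(npx)])
  } else .stopf("%s: unsupported bit depth %d", path, bits)
  if (photometric == "MONOCHROME1") {
    stored <- .dcm_us(bytes, els[["0028,0101"]]) %||% bits
    v <- (2^stored - 1) - v
  }
  frames <- array(NA_real_, c(rows, cols, nfr))
  for (k in seq_len(nfr)) {
    frames[, , k] <- t(matrix(v[(k - 1L) * rows * cols + seq_len(rows * cols)],
                              nrow = cols, ncol = rows))
  }

  times <- NULL
  ftv <- .dcm_num(bytes, els[["0018,1065"]])
  ft <- .dcm_num(bytes, els[["0018,1063"]])
  if (!is.null(ftv)) {
    if (length(ftv) != nfr)
      .stopf("%s: FrameTimeVector length %d != %d frames", path, length(ftv), nfr)
    times <- cumsum(ftv) / 1000
  } else if (!is.null(ft)) {
    times <- (seq_len(nfr) - 1L) * ft[1L] / 1000
  }

  list(frames = frames, times = times,
       view = .dcm_str(bytes, els[["0018,5101"]]),
       pixel_spacing_mm = .dcm_num(bytes, els[["0028,0030"]]),
       instance_number = .dcm_num(bytes, els[["0020,0013"]]))
}
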