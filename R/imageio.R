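# Slice I/O: DICOM in (minimal hand-written parser for uncompressed
# single-frame little-endian files, since no DICOM reader ships with the
# installed R stack), PNG/JPEG 8-bit grayscale working formats, 8-bit
# quantization and size normalization.

u16le <- function(raw, i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
u32le <- function(raw, i) {
  as.double(raw[i]) + 256 * as.double(raw[i + 1L]) +
    65536 * as.double(raw[i + 2L]) + 16777216 * as.double(raw[i + 3L])
}

longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one data element header starting at offset `pos` (1-based).
# Returns list(group, element, len, valuePos, nextPos).
dcmElement <- function(raw, pos, explicit) {
  if (pos + 7L > length(raw)) stopFormat("DICOM parse error: truncated element")
  group <- u16le(raw, pos)
  element <- u16le(raw, pos + 2L)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% longVRs) {
      len <- u32le(raw, pos + 8L)
      valuePos <- pos + 12L
    } else {
      len <- as.double(u16le(raw, pos + 6L))
      valuePos <- pos + 8L
    }
  } else {
    len <- u32le(raw, pos + 4L)
    valuePos <- pos + 8L
  }
  if (len == 4294967295) # undefined length (sequences) unsupported
    stopFormat("DICOM parse error: undefined-length element (",
               sprintf("%04x,%04x", group, element), ") not supported")
  list(group = group, element = element, len = len, valuePos = valuePos,
       nextPos = valuePos + len)
}

dcmString <- function(raw, el) {
  if (el$len == 0) return("")
  trimws(rawToChar(raw[el$valuePos:(el$valuePos + el$len - 1L)]))
}

#' Read a single-frame DICOM slice
#'
#' Minimal reader for uncompressed (implicit or explicit VR) little-endian
#' single-frame DICOM. Stored pixel values are rescaled with RescaleSlope
#' and RescaleIntercept, then mapped linearly to \[0, 1\]: by default over
#' the slice's own min-max range; passing a fixed `window = c(lo, hi)`
#' instead applies the same linear map to every slice of a series (values
#' outside the window are clipped), which keeps intensities comparable
#' across slices.
#'
#' @param path path to a DICOM file.
#' @param window optional length-2 numeric, fixed intensity window applied
#'   after rescaling.
#' @return An \linkS4class{MRISlice} (spacing and id filled from
#'   PixelSpacing and SOPInstanceUID when present).
#' @export
readDicomSlice <- function(path, window = NULL) {
  if (!file.exists(path)) stopFormat("file not found: ", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stopFormat("not a DICOM file (missing DICM marker): ", path)

  # File meta group (0002,xxxx) is always explicit VR little endian.
  pos <- 133L
  transferSyntax <- "1.2.840.10008.1.2.1"
  while (pos + 7L <= length(raw)) {
    el <- dcmElement(raw, pos, explicit = TRUE)
    if (el$group != 2L) break
    if (el$element == 0x0010) transferSyntax <- dcmString(raw, el)
    pos <- el$nextPos
  }
  explicit <- switch(transferSyntax,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stopFormat("unsupported DICOM transfer syntax (compressed or big-endian): ",
               transferSyntax))

  rows <- cols <- NA_integer_
  bitsAllocated <- 16L
  pixelRep <- 0L
  slope <- 1; intercept <- 0
  spacing <- NA_real_
  id <- ""
  pixelEl <- NULL
  while (pos + 7L <= length(raw)) {
    el <- dcmElement(raw, pos, explicit)
    tag <- el$group * 65536 + el$element
    if (el$group == 0x0028) {
      if (el$element == 0x0010) rows <- u16le(raw, el$valuePos)
      if (el$element == 0x0011) cols <- u16le(raw, el$valuePos)
      if (el$element == 0x0100) bitsAllocated <- u16le(raw, el$valuePos)
      if (el$element == 0x0103) pixelRep <- u16le(raw, el$valuePos)
      if (el$element == 0x0030)
        spacing <- as.numeric(strsplit(dcmString(raw, el), "\\\\")[[1]][1])
      if (el$element == 0x1052) intercept <- as.numeric(dcmString(raw, el))
      if (el$element == 0x1053) slope <- as.numeric(dcmString(raw, el))
    } else if (el$group == 0x0008 && el$element == 0x0018) {
      id <- dcmString(raw, el)
    } else if (el$group == 0x7FE0 && el$element == 0x0010) {
      pixelEl <- el
      break
    }
    pos <- el$nextPos
  }
  if (is.null(pixelEl)) stopFormat("DICOM file has no pixel data: ", path)
  if (is.na(rows) || is.na(cols))
    stopFormat("DICOM file missing Rows/Columns: ", path)
  if (!bitsAllocated %in% c(8L, 16L))
    stopFormat("unsupported BitsAllocated: ", bitsAllocated)
  bytes <- bitsAllocated / 8L
  need <- rows * cols * bytes
  if (pixelEl$valuePos + need - 1L > length(raw))
    stopFormat("DICOM pixel data truncated: ", path)
  con <- rawConnection(raw[pixelEl$valuePos:(pixelEl$valuePos + need - 1L)])
  on.exit(close(con))
  v <- readBin(con, "integer", n = rows * cols, size = bytes,
               signed = (pixelRep == 1L), endian = "little")
  m <- matrix(as.numeric(v), nrow = rows, ncol = cols, byrow = TRUE)
  m <- m * slope + intercept
  if (is.null(window)) {
    rng <- range(m)
    p <- if (diff(rng) == 0) matrix(0, rows, cols) else (m - rng[1]) / diff(rng)
  } else {
    p <- clip01((m - window[1]) / (window[2] - window[1]))
  }
  MRISlice(p, bitDepthSource = bitsAllocated, spacing = spacing, id = id)
}

#' Quantize a slice to 8 bits
#'
#' Maps each pixel to the nearest of 256 levels, `floor(p * 255 + 0.5) / 255`
#' (round-half-up, so 0.5 maps to level 128). Idempotent.
#'
#' @param slice an \linkS4class{MRISlice}.
#' @return An \linkS4class{MRISlice} with `bitDepthSource = 8`.
#' @export
to8bit <- function(slice) {
  q <- floor(pixels(slice) * 255 + 0.5) / 255
  MRISlice(q, bitDepthSource = 8L, spacing = slice@spacing,
           seqTag = slice@seqTag, id = slice@id)
}

#' Resize a slice with bicubic resampling
#'
#' Bicubic (Keys, a = -0.5) resampling with antialiasing when downscaling;
#' used for the uniform 256 x 256 input normalization.
#'
#' @param slice an \linkS4class{MRISlice}.
#' @param target side length in pixels (>= 2), or a length-2 vector
#'   c(rows, cols).
#' @return An \linkS4class{MRISlice} of exactly the target size; spacing is
#'   rescaled accordingly when known.
#' @export
resizeSlice <- function(slice, target) {
  target <- as.integer(target)
  if (length(target) == 1L) target <- c(target, target)
  if (any(target < 2L)) stopValidation("target: must be >= 2 pixels")
  p <- pixels(slice)
  out <- clip01(resampleGrid(p, target))
  sp <- if (is.na(slice@spacing)) NA_real_ else
    slice@spacing * nrow(p) / target[1]
  MRISlice(out, bitDepthSource = slice@bitDepthSource, spacing = sp,
           seqTag = slice@seqTag, id = slice@id)
}

#' Write a slice as an 8-bit grayscale image
#'
#' Quantizes to 8 bits (see \code{\link{to8bit}}) and writes PNG
#' (lossless; round-trips bit-exactly) or JPEG with an explicit quality
#' setting (default 95; the working-format default is PNG).
#'
#' @param slice an \linkS4class{MRISlice}.
#' @param path output file path.
#' @param format "png" or "jpeg".
#' @param quality JPEG quality in (0, 100\].
#' @return `path`, invisibly.
#' @export
writeSliceImage <- function(slice, path, format = c("png", "jpeg"),
                            quality = 95) {
  format <- match.arg(format)
  q <- pixels(to8bit(slice))
  if (format == "png") png::writePNG(q, path)
  else jpeg::writeJPEG(q, path, quality = quality / 100)
  invisible(path)
}

#' Read an 8-bit grayscale image as a slice
#'
#' Reads PNG or JPEG (chosen by magic bytes). Color inputs are converted
#' to luminance with the standard JPEG weights.
#'
#' @param path input file path.
#' @return An \linkS4class{MRISlice} with `bitDepthSource = 8`.
#' @export
readSliceImage <- function(path) {
  if (!file.exists(path)) stopFormat("file not found: ", path)
  magic <- readBin(path, "raw", 4L)
  img <- tryCatch({
    if (length(magic) >= 4L && identical(magic[1:4],
        as.raw(c(0x89, 0x50, 0x4E, 0x47)))) png::readPNG(path)
    else if (length(magic) >= 2L && identical(magic[1:2],
        as.raw(c(0xFF, 0xD8)))) jpeg::readJPEG(path)
    else stopFormat("unrecognized image format: ", path)
  }, error = function(e) {
    if (inherits(e, "mrisr_format_error")) stop(e)
    stopFormat("failed to read image (corrupt or truncated): ", path,
               " [", conditionMessage(e), "]")
  })
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  MRISlice(clip01(img), bitDepthSource = 8L,
           id = tools::file_path_sans_ext(basename(path)))
}
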