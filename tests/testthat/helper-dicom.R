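# Byte-crafted DICOM fixture writer, independent of the package's parser.
# Builds minimal single-frame little-endian files (explicit or implicit VR)
# directly from the encoding rules: preamble + "DICM", explicit-VR meta
# group with the transfer syntax, then the dataset elements and OW pixel
# data. Strings are padded to even length.

writeTestDicom <- function(path, pixelMatrix, bits = 16L, explicit = TRUE,
                           slope = NULL, intercept = NULL, spacing = NULL,
                           sopUID = "1.2.3.4.5", transferSyntax = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  padded <- function(s, null = FALSE) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, if (null) as.raw(0) else charToRaw(" "))
    r
  }
  # explicit-VR element with short (US/DS/UI/LO) value representation
  elExplicit <- function(group, element, vr, valueRaw) {
    w16(group); w16(element)
    writeBin(charToRaw(vr), con)
    w16(length(valueRaw))
    writeBin(valueRaw, con)
  }
  elImplicit <- function(group, element, valueRaw) {
    w16(group); w16(element)
    w32(length(valueRaw))
    writeBin(valueRaw, con)
  }
  u16raw <- function(x) {
    r <- raw(2)
    r[1] <- as.raw(x %% 256); r[2] <- as.raw(x %/% 256)
    r
  }

  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)

  ts <- if (!is.null(transferSyntax)) transferSyntax
        else if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  elExplicit(0x0002, 0x0010, "UI", padded(ts, null = TRUE))

  el <- if (explicit) {
    function(group, element, vr, valueRaw) elExplicit(group, element, vr, valueRaw)
  } else {
    function(group, element, vr, valueRaw) elImplicit(group, element, valueRaw)
  }

  el(0x0008, 0x0018, "UI", padded(sopUID, null = TRUE))
  rows <- nrow(pixelMatrix); cols <- ncol(pixelMatrix)
  el(0x0028, 0x0010, "US", u16raw(rows))
  el(0x0028, 0x0011, "US", u16raw(cols))
  if (!is.null(spacing))
    el(0x0028, 0x0030, "DS", padded(sprintf("%g\\%g", spacing, spacing)))
  el(0x0028, 0x0100, "US", u16raw(bits))
  el(0x0028, 0x0101, "US", u16raw(bits))
  el(0x0028, 0x0103, "US", u16raw(0L))
  if (!is.null(intercept)) el(0x0028, 0x1052, "DS", padded(sprintf("%g", intercept)))
  if (!is.null(slope)) el(0x0028, 0x1053, "DS", padded(sprintf("%g", slope)))

  # pixel data, row-major, unsigned little-endian
  v <- as.integer(t(pixelMatrix))
  nbytes <- length(v) * (bits / 8L)
  if (explicit) {
    w16(0x7FE0); w16(0x0010)
    writeBin(charToRaw("OW"), con)
    w16(0L)           # reserved
    w32(nbytes)
  } else {
    w16(0x7FE0); w16(0x0010)
    w32(nbytes)
  }
  if (bits == 16L) {
    # writeBin size 2 rejects values > 32767 when signed; encode manually
    lo <- v %% 256L; hi <- v %/% 256L
    bytes <- as.raw(rbind(lo, hi))
    writeBin(bytes, con)
  } else {
    writeBin(as.raw(v), con)
  }
  invisible(path)
}
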