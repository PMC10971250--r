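# Separable bicubic resampling (Keys kernel, a = -0.5). Downscaling widens
# the kernel support by the scale factor (antialiasing); windows are clipped
# at the image border and the surviving weights renormalized, the
# convolution-resampling convention shared by the major imaging toolchains.
# Resampling a dimension is a dense matrix product, so a full resize is
# Wr %*% img %*% t(Wc).

cubicKernel <- function(x, a = -0.5) {
  ax <- abs(x)
  r <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  r[i1] <- ((a + 2) * ax[i1] - (a + 3)) * ax[i1]^2 + 1
  r[i2] <- (((ax[i2] - 5) * ax[i2] + 8) * ax[i2] - 4) * a
  r
}

# Weight matrix mapping nIn samples to nOut samples along one axis.
resampleWeights <- function(nIn, nOut, antialias = TRUE) {
  scale <- nIn / nOut
  fscale <- if (antialias && scale > 1) scale else 1
  support <- 2 * fscale
  W <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    center <- (i - 0.5) * scale
    jmin <- max(0L, as.integer(floor(center - support + 0.5)))
    jmax <- min(nIn, as.integer(floor(center + support + 0.5)))
    j <- jmin:(jmax - 1L)
    w <- cubicKernel((j + 0.5 - center) / fscale)
    W[i, j + 1L] <- w / sum(w)
  }
  W
}

# Resize a matrix to outDim = c(rows, cols).
resampleGrid <- function(img, outDim, antialias = TRUE) {
  outDim <- as.integer(outDim)
  Wr <- resampleWeights(nrow(img), outDim[1], antialias)
  Wc <- resampleWeights(ncol(img), outDim[2], antialias)
  Wr %*% img %*% t(Wc)
}

#' Apply an affine draw (translation + isotropic zoom) to a slice
#'
#' The resampling used by data augmentation: the image is zoomed about its
#' centre by `zoom` and translated by (`tx`, `ty`) pixels (x = columns,
#' y = rows), with bicubic interpolation and zero fill outside the source.
#' Exposed separately from \code{\link{augmentSlice}} so a forced draw
#' (tx = ty = 0, zoom = 1), which is an exact identity, can be tested.
#'
#' @param slice an \linkS4class{MRISlice}.
#' @param tx,ty translation in pixels (content moves by +tx columns, +ty rows).
#' @param zoom isotropic scale factor about the image centre.
#' @return An \linkS4class{MRISlice} of unchanged size.
#' @export
applyAffine <- function(slice, tx = 0, ty = 0, zoom = 1) {
  img <- pixels(slice)
  out <- affineAxis(affineAxis(img, ty, zoom, byRow = TRUE), tx, zoom,
                    byRow = FALSE)
  MRISlice(clip01(out), bitDepthSource = slice@bitDepthSource,
           spacing = slice@spacing, seqTag = slice@seqTag, id = slice@id)
}

# One-axis affine resample: output position p samples the source at
# (p - c)/zoom + c - t  (c = centre). Keys cubic taps, out-of-range taps
# dropped (zero fill); the kernel's partition of unity makes the interior
# exact for integer draws.
affineAxis <- function(img, t, zoom, byRow = TRUE) {
  n <- if (byRow) nrow(img) else ncol(img)
  c0 <- (n + 1) / 2
  src <- (seq_len(n) - c0) / zoom + c0 - t
  W <- matrix(0, n, n)
  base <- floor(src)
  for (k in -1:2) {
    j <- base + k
    w <- cubicKernel(src - j)
    ok <- j >= 1 & j <= n
    if (any(ok)) W[cbind(which(ok), j[ok])] <- W[cbind(which(ok), j[ok])] + w[ok]
  }
  if (byRow) W %*% img else img %*% t(W)
}
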