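# Training-corpus construction: YCbCr separation, bicubic degradation,
# residual computation, augmentation and patch extraction. All grids stay
# real-valued; quantization never happens inside the training-pair path.

#' Convert a slice to YCbCr channels
#'
#' Grayscale slices map to y = pixels with neutral chrominance
#' (cb = cr = 0.5). Three-channel arrays (H x W x 3 RGB) use the standard
#' full-range JPEG transform.
#'
#' @param x an \linkS4class{MRISlice} or an H x W x 3 RGB array in \[0, 1\].
#' @return A \linkS4class{YCbCrImage}.
#' @export
toYCbCr <- function(x) {
  if (is(x, "MRISlice")) {
    p <- pixels(x)
    neutral <- matrix(0.5, nrow(p), ncol(p))
    return(new("YCbCrImage", y = p, cb = neutral, cr = neutral))
  }
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L) {
    R <- x[, , 1]; G <- x[, , 2]; B <- x[, , 3]
    y <- 0.299 * R + 0.587 * G + 0.114 * B
    cb <- (B - y) / 1.772 + 0.5              # 1.772 = 2 (1 - 0.114)
    cr <- (R - y) / 1.402 + 0.5              # 1.402 = 2 (1 - 0.299)
    return(new("YCbCrImage", y = y, cb = cb, cr = cr))
  }
  stopValidation("x: must be an MRISlice or an H x W x 3 array")
}

#' Recombine YCbCr channels into an image
#'
#' Chrominance within 1e-9 of neutral collapses to a grayscale
#' \linkS4class{MRISlice}; otherwise the inverse JPEG transform yields an
#' H x W x 3 RGB array.
#'
#' @param ycc a \linkS4class{YCbCrImage}.
#' @param ... metadata (bitDepthSource, spacing, seqTag, id) forwarded to
#'   the \linkS4class{MRISlice} constructor in the grayscale case.
#' @export
fromYCbCr <- function(ycc, ...) {
  stopifnot(is(ycc, "YCbCrImage"))
  if (max(abs(ycc@cb - 0.5)) < 1e-9 && max(abs(ycc@cr - 0.5)) < 1e-9)
    return(MRISlice(clip01(ycc@y), ...))
  cb <- ycc@cb - 0.5; cr <- ycc@cr - 0.5
  R <- ycc@y + 1.402 * cr                    # 1.402 = 2 (1 - 0.299), exact
  B <- ycc@y + 1.772 * cb                    # 1.772 = 2 (1 - 0.114), exact
  G <- (ycc@y - 0.299 * R - 0.114 * B) / 0.587
  out <- array(0, c(dim(ycc@y), 3L))
  out[, , 1] <- R; out[, , 2] <- G; out[, , 3] <- B
  clip01(out)
}

#' Bicubic degradation model
#'
#' Downscales a luminance grid by 1/scale (bicubic with antialiasing,
#' intermediate size `ceiling(dim / scale)` so non-divisible sizes are
#' handled) and bicubically upscales back to the original grid, yielding
#' the low-resolution input X whose dimensions equal the ground truth's.
#' The result is clipped to \[0, 1\] (as storage as an 8-bit image would).
#'
#' @param y a numeric matrix in \[0, 1\] (ground-truth luminance) or an
#'   \linkS4class{MRISlice}.
#' @param scale integer scale factor; 2, 3 or 4 unless `allowedScales`
#'   widens the set.
#' @param allowedScales integer vector of permitted scales.
#' @return A matrix of the same dimensions as `y`.
#' @export
degradeSlice <- function(y, scale, allowedScales = 2:4) {
  if (is(y, "MRISlice")) y <- pixels(y)
  if (!scale %in% allowedScales)
    stopValidation("scale: must be one of {",
                   paste(allowedScales, collapse = ", "), "}")
  if (any(dim(y) < scale)) stopValidation("y: grid dims must be >= scale")
  low <- resampleGrid(y, ceiling(dim(y) / scale), antialias = TRUE)
  clip01(resampleGrid(low, dim(y), antialias = TRUE))
}

#' Residual image
#'
#' Elementwise difference `yTrue - x`; the quantity the network learns to
#' predict. For inputs in \[0, 1\] the residual lies in \[-1, 1\].
#'
#' @param yTrue,x numeric matrices of identical shape.
#' @return The residual matrix.
#' @export
residualImage <- function(yTrue, x) {
  assertSameShape(yTrue, x, "yTrue and x")
  yTrue - x
}

#' Randomly augment a slice
#'
#' One affine draw per call: integer translations tx, ty uniform on
#' \[-30, 30\] px and an isotropic zoom uniform on \[0.9, 1.1\], applied
#' with bicubic resampling and zero fill (see \code{\link{applyAffine}}).
#' Deterministic per seed.
#'
#' @param slice an \linkS4class{MRISlice}.
#' @param seed integer seed controlling the draw.
#' @return An augmented \linkS4class{MRISlice} of unchanged size.
#' @export
augmentSlice <- function(slice, seed) {
  draw <- withSeed(seed, list(tx = sample(-30:30, 1), ty = sample(-30:30, 1),
                              zoom = runif(1, 0.9, 1.1)))
  applyAffine(slice, draw$tx, draw$ty, draw$zoom)
}

# Patch top-left corners along one axis for the given stride.
patchGrid <- function(n, size, stride) seq(1L, n - size + 1L, by = stride)

#' Extract aligned patches from a residual pair
#'
#' Cuts the (x, yTrue, r) grids into `size` x `size` patches on a regular
#' grid with the given stride; the count is
#' (floor((H - size)/stride) + 1) * (floor((W - size)/stride) + 1).
#'
#' @param pair a \linkS4class{ResidualPair}.
#' @param size patch side length (default 41).
#' @param stride grid stride (default `size`, i.e. non-overlapping).
#' @return A list of \linkS4class{ResidualPair} patches.
#' @export
extractPatches <- function(pair, size = 41L, stride = size) {
  stopifnot(is(pair, "ResidualPair"))
  d <- dim(pair@x)
  if (size > min(d)) stopValidation("size: patch larger than image dims")
  rows <- patchGrid(d[1], size, stride)
  cols <- patchGrid(d[2], size, stride)
  out <- vector("list", length(rows) * length(cols))
  k <- 1L
  for (j in cols) for (i in rows) {
    ri <- i:(i + size - 1L); cj <- j:(j + size - 1L)
    out[[k]] <- new("ResidualPair", x = pair@x[ri, cj],
                    yTrue = pair@yTrue[ri, cj], r = pair@r[ri, cj],
                    scale = pair@scale)
    k <- k + 1L
  }
  out
}

#' Build a training set of residual-pair patches
#'
#' For each slice, each augmentation replicate and each scale factor:
#' augment the ground truth, take its luminance, degrade it bicubically,
#' form the residual and extract aligned patches. Patches from all
#' combinations are pooled and shuffled deterministically under `seed`.
#'
#' @param slices list of \linkS4class{MRISlice} ground-truth slices.
#' @param scales subset of c(2, 3, 4).
#' @param nAugment augmentation replicates per slice in addition to the
#'   original (0 = originals only).
#' @param seed integer seed for augmentation draws and the final shuffle.
#' @param patchSize patch side length (default 41).
#' @param stride patch grid stride (default `patchSize`).
#' @return A \linkS4class{TrainingSet}.
#' @export
buildTrainingSet <- function(slices, scales = c(2L, 3L, 4L), nAugment = 0L,
                             seed = 1L, patchSize = 41L, stride = patchSize) {
  if (length(slices) == 0L) stopValidation("slices: at least one required")
  if (!all(scales %in% 2:4)) stopValidation("scales: must be a subset of {2,3,4}")
  xs <- list(); ys <- list(); rs <- list(); sc <- integer(0)
  manRows <- list()
  for (si in seq_along(slices)) {
    versions <- list(list(slice = slices[[si]], aug = 0L, augSeed = NA_integer_))
    for (a in seq_len(nAugment)) {
      as_ <- deriveSeed(seed, si * 1000L + a)
      versions[[a + 1L]] <- list(slice = augmentSlice(slices[[si]], as_),
                                 aug = a, augSeed = as_)
    }
    for (v in versions) {
      yFull <- toYCbCr(v$slice)@y
      for (s in scales) {
        x <- degradeSlice(yFull, s)
        pair <- residualPair(x, yFull, s)
        patches <- extractPatches(pair, patchSize, stride)
        for (p in patches) {
          xs[[length(xs) + 1L]] <- p@x
          ys[[length(ys) + 1L]] <- p@yTrue
          rs[[length(rs) + 1L]] <- p@r
          sc <- c(sc, as.integer(s))
        }
        manRows[[length(manRows) + 1L]] <- data.frame(
          slice_id = sliceId(slices[[si]]), aug = v$aug, aug_seed = v$augSeed,
          scale = as.integer(s), n_patches = length(patches),
          stringsAsFactors = FALSE)
      }
    }
  }
  n <- length(xs)
  perm <- withSeed(seed, sample.int(n))
  toArr <- function(lst) array(unlist(lst[perm], use.names = FALSE),
                               dim = c(patchSize, patchSize, n))
  man <- do.call(rbind, manRows)
  man$shuffle_seed <- as.integer(seed)
  new("TrainingSet", x = toArr(xs), yTrue = toArr(ys), r = toArr(rs),
      scale = sc[perm], patchSize = as.integer(patchSize), manifest = man)
}

#' Persist a training set to a directory
#'
#' Layout (documented, version 1): `x.bin`, `y.bin`, `r.bin` hold the
#' patch arrays as little-endian doubles in column-major order;
#' `meta.json` records the format version, dimensions, patch size and
#' per-patch scales; `manifest.csv` is the provenance table.
#'
#' @param ts a \linkS4class{TrainingSet}.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeTrainingSet <- function(ts, dir) {
  stopifnot(is(ts, "TrainingSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wb <- function(a, f) {
    con <- file(file.path(dir, f), "wb")
    on.exit(close(con))
    writeBin(as.vector(a), con, size = 8L, endian = "little")
  }
  wb(ts@x, "x.bin"); wb(ts@yTrue, "y.bin"); wb(ts@r, "r.bin")
  jsonlite::write_json(
    list(format = "mrisr-training-set", version = 1L, dim = dim(ts@x),
         patch_size = ts@patchSize, scale = ts@scale),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  write.csv(ts@manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a training set written by \code{\link{writeTrainingSet}}
#'
#' @param dir directory containing the versioned layout.
#' @return A \linkS4class{TrainingSet}.
#' @export
readTrainingSet <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stopFormat("not a training-set directory: ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$format, "mrisr-training-set"))
    stopFormat("unrecognized training-set format in ", metaPath)
  d <- as.integer(meta$dim)
  rb <- function(f) {
    con <- file(file.path(dir, f), "rb")
    on.exit(close(con))
    array(readBin(con, "double", n = prod(d), size = 8L, endian = "little"),
          dim = d)
  }
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  new("TrainingSet", x = rb("x.bin"), yTrue = rb("y.bin"), r = rb("r.bin"),
      scale = as.integer(meta$scale), patchSize = as.integer(meta$patch_size),
      manifest = man)
}
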