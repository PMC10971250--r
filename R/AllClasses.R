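# S4 classes for the pipeline's central objects. Tabular results
# (quality records, evaluation summaries, manifests) are plain data.frames.

#' MRISlice: a single 2-D grayscale image slice
#'
#' The unit of all processing: a rectangular grid of pixel intensities in
#' \[0, 1\] together with its source bit depth, optional pixel spacing
#' (mm/px), an optional sequence tag (T2, T1, CET1, VISTA, PD) and an id.
#'
#' @slot pixels numeric matrix with all values in \[0, 1\].
#' @slot bitDepthSource integer, 8 or 16; the bit depth of the source data.
#' @slot spacing numeric, mm per pixel (NA when unknown).
#' @slot seqTag character sequence tag ("" when unknown).
#' @slot id character identifier.
#' @export
setClass("MRISlice",
  representation(pixels = "matrix", bitDepthSource = "integer",
                 spacing = "numeric", seqTag = "character", id = "character"),
  prototype(bitDepthSource = 8L, spacing = NA_real_, seqTag = "", id = ""))

setValidity("MRISlice", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(p) == 0L)
    return("pixels: must be a non-empty numeric matrix")
  if (anyNA(p) || any(!is.finite(p)))
    return("pixels: must be finite")
  if (min(p) < 0 || max(p) > 1)
    return("pixels: values must lie in [0, 1]")
  if (!object@bitDepthSource %in% c(8L, 16L))
    return("bitDepthSource: must be 8 or 16")
  TRUE
})

#' Construct an MRISlice
#'
#' @param pixels numeric matrix in \[0, 1\].
#' @param bitDepthSource 8 or 16.
#' @param spacing mm per pixel, or NA.
#' @param seqTag sequence tag, one of "", "T2", "T1", "CET1", "VISTA", "PD".
#' @param id slice identifier.
#' @return An \linkS4class{MRISlice}.
#' @examples
#' s <- MRISlice(matrix(0.5, 8, 8), id = "flat")
#' dim(pixels(s))
#' @export
MRISlice <- function(pixels, bitDepthSource = 8L, spacing = NA_real_,
                     seqTag = "", id = "") {
  new("MRISlice", pixels = pixels, bitDepthSource = as.integer(bitDepthSource),
      spacing = as.numeric(spacing), seqTag = seqTag, id = id)
}

#' TargetCoordinate: a real-valued point target position
#'
#' Sub-pixel (x, y) position in pixel coordinates (x = column, y = row),
#' with optional spacing (mm/px) for millimetre conversion. Stands in for
#' the stereotactic frame coordinates used to verify that reconstruction
#' does not displace a target.
#'
#' @slot x,y numeric pixel coordinates.
#' @slot spacing numeric mm per pixel (NA when unknown).
#' @export
setClass("TargetCoordinate",
  representation(x = "numeric", y = "numeric", spacing = "numeric"),
  prototype(spacing = NA_real_))

setValidity("TargetCoordinate", function(object) {
  if (length(object@x) != 1L || length(object@y) != 1L ||
      !is.finite(object@x) || !is.finite(object@y))
    return("x, y: must be single finite numbers")
  TRUE
})

#' @param x,y pixel coordinates.
#' @param spacing mm per pixel.
#' @rdname TargetCoordinate-class
#' @export
targetCoordinate <- function(x, y, spacing = NA_real_) {
  new("TargetCoordinate", x = as.numeric(x), y = as.numeric(y),
      spacing = as.numeric(spacing))
}

#' PhantomSpec: full parameterization of one synthetic slice
#'
#' Everything needed to regenerate a phantom bit-identically: the seed,
#' image size, sequence preset, per-region tissue intensities, Rician
#' noise scale, an optional curvilinear filament (a thin, high-contrast
#' trigeminal-nerve analog) and an optional Gaussian fiducial target.
#'
#' @slot seed integer RNG seed.
#' @slot size integer pixels per side (>= 64).
#' @slot sequence one of "T2", "T1", "CET1", "VISTA", "PD".
#' @slot tissueLevels named numeric vector of region mean intensities in
#'   \[0, 1\]; names are background, scalp, wm, gm, csf.
#' @slot noiseSigma Rician noise scale (>= 0), intensity units.
#' @slot geometryScale multiplier on all region radii (cohort variability).
#' @slot filament list(points = k x 2 matrix of (x, y) control points,
#'   width = px, intensity = level) or empty list for none.
#' @slot fiducial list(x, y, amplitude, sigma) or empty list for none.
#' @export
setClass("PhantomSpec",
  representation(seed = "integer", size = "integer", sequence = "character",
                 tissueLevels = "numeric", noiseSigma = "numeric",
                 geometryScale = "numeric", filament = "list",
                 fiducial = "list"))

setValidity("PhantomSpec", function(object) {
  if (object@size < 64L) return("size: must be >= 64")
  if (!object@sequence %in% c("T2", "T1", "CET1", "VISTA", "PD"))
    return("sequence: must be one of T2, T1, CET1, VISTA, PD")
  tl <- object@tissueLevels
  need <- c("background", "scalp", "wm", "gm", "csf")
  if (!all(need %in% names(tl)))
    return(paste0("tissueLevels: must name ", paste(need, collapse = ", ")))
  if (any(tl < 0) || any(tl > 1))
    return("tissueLevels: all levels must lie in [0, 1]")
  if (object@noiseSigma < 0) return("noiseSigma: must be >= 0")
  if (object@geometryScale < 0.8 || object@geometryScale > 1.2)
    return("geometryScale: must lie in [0.8, 1.2]")
  if (length(object@filament)) {
    f <- object@filament
    if (!all(c("points", "width", "intensity") %in% names(f)))
      return("filament: needs points, width, intensity")
    if (!is.matrix(f$points) || ncol(f$points) != 2L || nrow(f$points) < 2L)
      return("filament: points must be a k x 2 matrix, k >= 2")
    if (f$width <= 0) return("filament: width must be > 0")
    if (f$intensity < 0 || f$intensity > 1)
      return("filament: intensity must lie in [0, 1]")
  }
  if (length(object@fiducial)) {
    fd <- object@fiducial
    if (!all(c("x", "y", "amplitude", "sigma") %in% names(fd)))
      return("fiducial: needs x, y, amplitude, sigma")
    if (fd$x < 1 || fd$x > object@size || fd$y < 1 || fd$y > object@size)
      return("fiducial: (x, y) must lie inside image bounds")
    if (fd$sigma <= 0) return("fiducial: sigma must be > 0")
  }
  TRUE
})

#' YCbCrImage: luminance/chrominance channel decomposition
#'
#' @slot y,cb,cr numeric matrices of identical shape, values in \[0, 1\].
#'   For grayscale sources cb and cr equal the neutral constant 0.5.
#' @export
setClass("YCbCrImage",
  representation(y = "matrix", cb = "matrix", cr = "matrix"))

setValidity("YCbCrImage", function(object) {
  if (!identical(dim(object@y), dim(object@cb)) ||
      !identical(dim(object@y), dim(object@cr)))
    return("y, cb, cr: channels must share dimensions")
  TRUE
})

#' ResidualPair: one training example
#'
#' An upsampled low-resolution luminance grid `x`, its ground truth
#' `yTrue`, the residual `r = yTrue - x` (exact in working precision) and
#' the scale factor that produced the degradation.
#'
#' @slot x,yTrue,r numeric matrices of identical shape.
#' @slot scale integer scale factor (2, 3 or 4).
#' @export
setClass("ResidualPair",
  representation(x = "matrix", yTrue = "matrix", r = "matrix",
                 scale = "integer"))

setValidity("ResidualPair", function(object) {
  if (!identical(dim(object@x), dim(object@yTrue)) ||
      !identical(dim(object@x), dim(object@r)))
    return("x, yTrue, r: must share dimensions")
  if (!identical(object@r, object@yTrue - object@x))
    return("r: must equal yTrue - x bit-exactly")
  if (!object@scale %in% 2:4) return("scale: must be 2, 3 or 4")
  TRUE
})

residualPair <- function(x, yTrue, scale) {
  new("ResidualPair", x = x, yTrue = yTrue, r = yTrue - x,
      scale = as.integer(scale))
}

#' TrainingSet: pooled residual-pair patches
#'
#' @slot x,yTrue,r numeric arrays of shape patch x patch x n.
#' @slot scale integer vector, per-patch scale factor.
#' @slot patchSize integer patch side length.
#' @slot manifest data.frame provenance (source slice, augmentation seed,
#'   scale, patch count per combination).
#' @export
setClass("TrainingSet",
  representation(x = "array", yTrue = "array", r = "array",
                 scale = "integer", patchSize = "integer",
                 manifest = "data.frame"))

setValidity("TrainingSet", function(object) {
  dx <- dim(object@x)
  if (length(dx) != 3L) return("x: must be a 3-d array (patch, patch, n)")
  if (!identical(dx, dim(object@r)) || !identical(dx, dim(object@yTrue)))
    return("x, yTrue, r: arrays must share dimensions")
  if (dx[1] != object@patchSize || dx[2] != object@patchSize)
    return("patchSize: inconsistent with stored patch dimensions")
  if (length(object@scale) != dx[3])
    return("scale: one entry per stored pair required")
  if (!identical(object@r, object@yTrue - object@x))
    return("r: must equal yTrue - x bit-exactly for every stored pair")
  TRUE
})

#' VDSRModel: weights of the residual network
#'
#' Depth-d fully-convolutional network: layer 1 maps 1 -> width channels,
#' layers 2..d-1 map width -> width, layer d maps width -> 1; every layer
#' is a zero-padded 3x3 convolution, hidden layers are followed by ReLU
#' and the final reconstruction layer is linear. Weights for a layer are
#' stored as a (9*Cin) x Cout matrix whose row index encodes the kernel
#' tap (row offset, column offset, input channel) in column-major order.
#'
#' @slot depth integer number of convolution layers (>= 2).
#' @slot width integer filters per hidden layer.
#' @slot weights list of length depth; each element list(W = matrix, b = numeric).
#' @slot initSeed integer seed used for initialization.
#' @export
setClass("VDSRModel",
  representation(depth = "integer", width = "integer", weights = "list",
                 initSeed = "integer"))

setValidity("VDSRModel", function(object) {
  d <- object@depth; w <- object@width
  if (d < 2L) return("depth: must be >= 2")
  if (w < 1L) return("width: must be >= 1")
  if (length(object@weights) != d) return("weights: one entry per layer required")
  for (l in seq_len(d)) {
    cin <- if (l == 1L) 1L else w
    cout <- if (l == d) 1L else w
    W <- object@weights[[l]]$W
    b <- object@weights[[l]]$b
    if (!is.matrix(W) || nrow(W) != 9L * cin || ncol(W) != cout)
      return(sprintf("weights: layer %d must be a %d x %d matrix", l, 9 * cin, cout))
    if (length(b) != cout)
      return(sprintf("weights: layer %d bias must have length %d", l, cout))
  }
  TRUE
})

#' TrainConfig: the SGDM training recipe
#'
#' Defaults follow the full-scale training recipe: 100 epochs, mini-batch 64, momentum
#' 0.9, L2 regularization 1e-4, gradient L2-norm clipping at 0.01,
#' initial learning rate 0.1 dropping by a factor of 10 every 10 epochs.
#'
#' @slot maxEpochs,batchSize,lrDropPeriod integers.
#' @slot momentum,l2,gradientThreshold,initialLR,lrDropFactor,validationFraction numerics.
#' @slot shuffleSeed integer seed for splits and epoch shuffles.
#' @slot returnBest logical; return best-validation rather than final weights.
#' @export
setClass("TrainConfig",
  representation(maxEpochs = "integer", batchSize = "integer",
                 momentum = "numeric", l2 = "numeric",
                 gradientThreshold = "numeric", initialLR = "numeric",
                 lrDropFactor = "numeric", lrDropPeriod = "integer",
                 shuffleSeed = "integer", validationFraction = "numeric",
                 returnBest = "logical"))

setValidity("TrainConfig", function(object) {
  if (object@maxEpochs < 1L) return("maxEpochs: must be >= 1")
  if (object@batchSize < 1L) return("batchSize: must be >= 1")
  if (object@initialLR < 0) return("initialLR: must be >= 0")
  # initialLR 0 is permitted as the degenerate no-update limit
  if (object@gradientThreshold <= 0) return("gradientThreshold: must be > 0")
  if (object@l2 < 0) return("l2: must be >= 0")
  if (object@momentum < 0 || object@momentum >= 1)
    return("momentum: must lie in [0, 1)")
  if (object@lrDropFactor <= 0 || object@lrDropFactor > 1)
    return("lrDropFactor: must lie in (0, 1]")
  if (object@lrDropPeriod < 1L) return("lrDropPeriod: must be >= 1")
  if (object@validationFraction < 0 || object@validationFraction >= 1)
    return("validationFraction: must lie in [0, 1)")
  TRUE
})

#' TrainHistory: per-epoch training record
#'
#' @slot epochs data.frame with columns epoch, lr, trainLoss, valLoss.
#' @slot gradNorms numeric, post-clip global gradient L2 norm per step.
#' @slot initialValLoss numeric validation loss before the first update.
#' @export
setClass("TrainHistory",
  representation(epochs = "data.frame", gradNorms = "numeric",
                 initialValLoss = "numeric"))

#' SRResult: a reconstructed slice
#'
#' @slot image the reconstructed \linkS4class{MRISlice}.
#' @slot scale integer scale factor.
#' @slot modelId character hash of the producing checkpoint.
#' @slot clippedFraction fraction of pixels clipped at \[0, 1\].
#' @export
setClass("SRResult",
  representation(image = "MRISlice", scale = "integer", modelId = "character",
                 clippedFraction = "numeric"))

setValidity("SRResult", function(object) {
  if (object@clippedFraction < 0 || object@clippedFraction > 1)
    return("clippedFraction: must lie in [0, 1]")
  TRUE
})

#' MetricConfig: PSNR/SSIM configuration
#'
#' @slot peak maximum possible pixel value (1 for normalized, 255 for 8-bit).
#' @slot dynamicRange the L entering the SSIM stabilizing constants.
#' @slot k1,k2 SSIM constant factors (C1 = (k1 L)^2, C2 = (k2 L)^2, C3 = C2/2).
#' @slot alpha,beta,gamma exponents on luminance/contrast/structure terms.
#' @slot ssimMode "windowed" (11x11 Gaussian, sigma 1.5; field standard) or
#'   "global" (one moment triple over the whole image; equation-literal).
#' @slot windowSize,windowSigma Gaussian window parameters (windowed mode).
#' @export
setClass("MetricConfig",
  representation(peak = "numeric", dynamicRange = "numeric",
                 k1 = "numeric", k2 = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 ssimMode = "character", windowSize = "integer",
                 windowSigma = "numeric"))

setValidity("MetricConfig", function(object) {
  if (object@peak <= 0) return("peak: must be > 0")
  if (object@dynamicRange <= 0) return("dynamicRange: must be > 0")
  if (!object@ssimMode %in% c("windowed", "global"))
    return("ssimMode: must be 'windowed' or 'global'")
  if (object@windowSize < 3L || object@windowSize %% 2L == 0L)
    return("windowSize: must be an odd integer >= 3")
  TRUE
})
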