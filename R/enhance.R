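# Inference path: bicubic upscaling of all channels, residual prediction
# on the luminance channel only, recombination Ybar = clip(Y + f(Y), 0, 1),
# and reassembly with the (neutral, for grayscale MRI) chrominance.

#' Super-resolve a slice with a trained residual network
#'
#' The input is either a degraded grid already at the target size (the
#' degrade-then-restore evaluation protocol; `upsampled = TRUE`) or a
#' genuinely small grid that is first bicubically upscaled by `scale`.
#' The slice is split into YCbCr, the network predicts the luminance
#' residual on the full grid (no patching; the network is fully
#' convolutional), the residual is added back, the result clipped to
#' \[0, 1\] and recombined with the chrominance channels.
#'
#' @param model a trained \linkS4class{VDSRModel} (or a checkpoint path,
#'   which is loaded and hash-verified).
#' @param input an \linkS4class{MRISlice}.
#' @param scale integer scale factor (2, 3 or 4).
#' @param upsampled is `input` already at the target grid size?
#' @return An \linkS4class{SRResult}; its `clippedFraction` slot reports
#'   the proportion of pixels that fell outside \[0, 1\] before clipping.
#' @examples
#' m <- initVDSR(depth = 3, width = 4, seed = 1)   # untrained: f(X) = 0
#' s <- generatePhantom(phantomSpec(seed = 1, size = 64, noiseSigma = 0))
#' x <- degradeSlice(s, 2)
#' sr <- superResolve(m, MRISlice(x), 2)
#' identical(pixels(sr), x)  # untrained model == bicubic restoration
#' @export
superResolve <- function(model, input, scale, upsampled = TRUE) {
  if (is.character(model)) model <- readCheckpoint(model)
  stopifnot(is(model, "VDSRModel"), is(input, "MRISlice"))
  if (!scale %in% 2:4) stopValidation("scale: must be 2, 3 or 4")
  ycc <- toYCbCr(input)
  if (!upsampled) {
    target <- dim(ycc@y) * scale
    ycc <- new("YCbCrImage",
               y = clip01(resampleGrid(ycc@y, target)),
               cb = clip01(resampleGrid(ycc@cb, target)),
               cr = clip01(resampleGrid(ycc@cr, target)))
  }
  f <- vdsrForward(model, ycc@y)
  raw <- ycc@y + f
  clipped <- mean(raw < 0 | raw > 1)
  yBar <- clip01(raw)
  out <- fromYCbCr(new("YCbCrImage", y = yBar, cb = ycc@cb, cr = ycc@cr),
                   bitDepthSource = input@bitDepthSource,
                   spacing = input@spacing, seqTag = input@seqTag,
                   id = paste0(input@id, "_sr"))
  new("SRResult", image = out, scale = as.integer(scale),
      modelId = modelHash(model), clippedFraction = clipped)
}
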