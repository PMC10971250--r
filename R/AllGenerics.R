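# Accessor generics and show methods.

#' Pixel matrix of a slice
#' @param x an \linkS4class{MRISlice} or \linkS4class{SRResult}.
#' @return numeric matrix in \[0, 1\].
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "MRISlice", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "SRResult", function(x) x@image@pixels)

#' Pixel spacing (mm/px) of a slice
#' @param x an \linkS4class{MRISlice}.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "MRISlice", function(x) x@spacing)

#' Sequence tag of a slice
#' @param x an \linkS4class{MRISlice} or \linkS4class{PhantomSpec}.
#' @export
setGeneric("seqTag", function(x) standardGeneric("seqTag"))

#' @rdname seqTag
#' @export
setMethod("seqTag", "MRISlice", function(x) x@seqTag)

#' @rdname seqTag
#' @export
setMethod("seqTag", "PhantomSpec", function(x) x@sequence)

#' Slice identifier
#' @param x an \linkS4class{MRISlice}.
#' @export
setGeneric("sliceId", function(x) standardGeneric("sliceId"))

#' @rdname sliceId
#' @export
setMethod("sliceId", "MRISlice", function(x) x@id)

#' Number of trainable parameters of a model
#' @param model a \linkS4class{VDSRModel}.
#' @return integer count of weights plus biases.
#' @examples
#' nParams(initVDSR(depth = 2, width = 1, seed = 1))  # 20
#' @export
nParams <- function(model) {
  stopifnot(is(model, "VDSRModel"))
  sum(vapply(model@weights,
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Per-layer kernels as a 4-d array
#'
#' Reshapes a layer's stored (9*Cin) x Cout weight matrix into the
#' conventional 3 x 3 x Cin x Cout filter bank.
#' @param model a \linkS4class{VDSRModel}.
#' @param layer layer index in 1..depth.
#' @export
kernelArray <- function(model, layer) {
  W <- model@weights[[layer]]$W
  cin <- nrow(W) / 9L
  array(W, dim = c(3L, 3L, cin, ncol(W)))
}

#' Number of stored training pairs
#' @param x a \linkS4class{TrainingSet}.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname nPairs
#' @export
setMethod("nPairs", "TrainingSet", function(x) dim(x@x)[3])

#' Provenance manifest of a training set
#' @param x a \linkS4class{TrainingSet}.
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname manifest
#' @export
setMethod("manifest", "TrainingSet", function(x) x@manifest)

setMethod("show", "MRISlice", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MRISlice '%s': %d x %d, source %d-bit, sequence %s\n",
              object@id, d[1], d[2], object@bitDepthSource,
              if (nzchar(object@seqTag)) object@seqTag else "<none>"))
  cat(sprintf("  intensity range [%.4f, %.4f]", min(object@pixels),
              max(object@pixels)))
  if (!is.na(object@spacing)) cat(sprintf(", spacing %.3f mm/px", object@spacing))
  cat("\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d, sequence %s, seed %d, noise sigma %.4g\n",
              object@size, object@size, object@sequence, object@seed,
              object@noiseSigma))
  cat(sprintf("  filament: %s; fiducial: %s\n",
              if (length(object@filament)) "yes" else "no",
              if (length(object@fiducial))
                sprintf("(%.1f, %.1f)", object@fiducial$x, object@fiducial$y)
              else "no"))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d residual pairs of %d x %d patches; scales {%s}\n",
              nPairs(object), object@patchSize, object@patchSize,
              paste(sort(unique(object@scale)), collapse = ", ")))
})

setMethod("show", "VDSRModel", function(object) {
  cat(sprintf("VDSRModel: depth %d, width %d, 3x3 kernels, %d parameters (seed %d)\n",
              object@depth, object@width, nParams(object), object@initSeed))
})

setMethod("show", "TrainHistory", function(object) {
  n <- nrow(object@epochs)
  cat(sprintf("TrainHistory: %d epochs; initial val loss %.6g", n,
              object@initialValLoss))
  if (n > 0)
    cat(sprintf(", final val loss %.6g", object@epochs$valLoss[n]))
  cat("\n")
})

setMethod("show", "SRResult", function(object) {
  cat(sprintf("SRResult: scale x%d, model %s, clipped fraction %.4f\n",
              object@scale, substr(object@modelId, 1, 8),
              object@clippedFraction))
  show(object@image)
})
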