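# The depth-20 residual network f. Hidden layers are zero-padded 3x3
# convolutions (64 filters) followed by ReLU; the final reconstruction
# layer is a linear 3x3 convolution with a single output channel, so the
# predicted residual can be added back to the single-channel luminance
# input. Forward/backward arithmetic lives in src/vdsr.cpp.

#' Initialize a residual super-resolution network
#'
#' Hidden-layer weights are drawn He-normal (sd = sqrt(2 / (9 * fan_in)))
#' under the given seed; all biases are zero. The final reconstruction
#' layer is zero-initialized, so the untrained residual branch outputs
#' exactly zero and the untrained model coincides with plain bicubic
#' restoration (training can then only improve on that baseline).
#'
#' @param depth number of convolution layers (default 20).
#' @param width filters per hidden layer (default 64).
#' @param seed integer initialization seed.
#' @return A \linkS4class{VDSRModel}.
#' @examples
#' m <- initVDSR(depth = 20, width = 64, seed = 1)
#' nParams(m)  # 665921
#' @export
initVDSR <- function(depth = 20L, width = 64L, seed = 1L) {
  depth <- as.integer(depth); width <- as.integer(width)
  if (depth < 2L) stopValidation("depth: must be >= 2")
  if (width < 1L) stopValidation("width: must be >= 1")
  weights <- withSeed(seed, lapply(seq_len(depth), function(l) {
    cin <- if (l == 1L) 1L else width
    cout <- if (l == depth) 1L else width
    if (l == depth) {
      W <- matrix(0, 9L * cin, cout)
    } else {
      W <- matrix(rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                  9L * cin, cout)
    }
    list(W = W, b = numeric(cout))
  }))
  new("VDSRModel", depth = depth, width = width, weights = weights,
      initSeed = as.integer(seed))
}

modelWb <- function(model) {
  list(W = lapply(model@weights, `[[`, "W"),
       b = lapply(model@weights, `[[`, "b"))
}

#' Forward pass of the residual network
#'
#' Fully convolutional: accepts any spatial size (a single H x W matrix or
#' an H x W x N batch array of single-channel images) and preserves it, so
#' a model trained on 41 x 41 patches runs unchanged on full 256 x 256
#' grids.
#'
#' @param model a \linkS4class{VDSRModel}.
#' @param x numeric matrix, or 3-d array whose third dimension indexes the
#'   batch.
#' @return The predicted residual f(x), same shape as `x`.
#' @export
vdsrForward <- function(model, x) {
  stopifnot(is(model, "VDSRModel"))
  wb <- modelWb(model)
  if (is.matrix(x)) {
    out <- cpp_vdsr_forward(wb$W, wb$b, array(x, c(dim(x), 1L)))
    return(out[, , 1])
  }
  if (is.array(x) && length(dim(x)) == 3L)
    return(cpp_vdsr_forward(wb$W, wb$b, x))
  stopValidation("x: must be a single-channel matrix or an H x W x N array")
}

#' Training loss
#'
#' Half the mean squared difference between the predicted and the target
#' residual, averaged over all pixels (and batch entries), so the loss
#' scale -- and with it the clipping threshold and learning rate -- is
#' resolution-independent.
#'
#' @param pred,r numeric arrays of identical shape.
#' @return Non-negative scalar; zero iff `pred` equals `r`.
#' @export
vdsrLoss <- function(pred, r) {
  assertSameShape(pred, r, "pred and r")
  0.5 * mean((pred - r)^2)
}

#' Loss and analytic gradients on a batch
#'
#' Returns the loss 0.5 * mean((f(x) - r)^2) together with its gradient
#' with respect to every layer's weights and biases. Used by the SGDM
#' training loop and by finite-difference gradient checks.
#'
#' @param model a \linkS4class{VDSRModel}.
#' @param x,r batch arrays (H x W x N) of inputs and target residuals.
#' @return list(loss, gW = list of matrices, gb = list of vectors).
#' @export
vdsrLossGrad <- function(model, x, r) {
  stopifnot(is(model, "VDSRModel"))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (is.matrix(r)) r <- array(r, c(dim(r), 1L))
  assertSameShape(x, r, "x and r")
  wb <- modelWb(model)
  cpp_vdsr_loss_grad(wb$W, wb$b, x, r)
}

#' Write a model checkpoint
#'
#' Documented container (version 1): depth, width, init seed, per-layer
#' arrays, optional training provenance, and an MD5 hash of the serialized
#' weights that \code{\link{readCheckpoint}} verifies on load.
#'
#' @param model a \linkS4class{VDSRModel}.
#' @param path output file path.
#' @param provenance optional list recorded verbatim (e.g. training seeds).
#' @return The weight hash, invisibly.
#' @export
writeCheckpoint <- function(model, path, provenance = NULL) {
  stopifnot(is(model, "VDSRModel"))
  h <- objectHash(model@weights)
  obj <- list(format = "mrisr-vdsr-checkpoint", version = 1L,
              depth = model@depth, width = model@width,
              initSeed = model@initSeed, provenance = provenance,
              weightHash = h, weights = model@weights)
  saveRDS(obj, path)
  invisible(h)
}

#' Read and verify a model checkpoint
#'
#' @param path checkpoint file written by \code{\link{writeCheckpoint}}.
#' @return A \linkS4class{VDSRModel}; the stored weight hash is recomputed
#'   and a mismatch (corrupt or tampered checkpoint) raises an error.
#' @export
readCheckpoint <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stopFormat("unreadable checkpoint: ",
                                                 path))
  if (!identical(obj$format, "mrisr-vdsr-checkpoint"))
    stopFormat("not a model checkpoint: ", path)
  if (!identical(objectHash(obj$weights), obj$weightHash))
    stopFormat("checkpoint hash mismatch (corrupt weights): ", path)
  new("VDSRModel", depth = obj$depth, width = obj$width,
      weights = obj$weights, initSeed = obj$initSeed)
}

#' Hash of a model's weights
#'
#' @param model a \linkS4class{VDSRModel}.
#' @return MD5 string identifying the exact weights.
#' @export
modelHash <- function(model) objectHash(model@weights)
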