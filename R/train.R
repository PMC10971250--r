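# SGDM training with the full-scale recipe as defaults: momentum 0.9, L2 regularization
# 1e-4, per-batch global gradient L2-norm clipping at 0.01, learning rate
# 0.1 dropping by a factor of 10 every 10 epochs, mini-batch 64, up to
# 100 epochs. Per step, in documented order: (1) add the L2-decay term to
# the weight gradients, (2) clip the global gradient L2 norm, (3) momentum
# update, (4) weight update.

#' Construct a training configuration
#'
#' Defaults are the full-scale recipe (see class docs). `deskTrainConfig()`
#' provides the desk-scale profile used by the package's own experiments.
#'
#' @param maxEpochs,batchSize,momentum,l2,gradientThreshold,initialLR
#'   optimizer settings.
#' @param lrDropFactor,lrDropPeriod learning-rate schedule: lr at epoch e is
#'   `initialLR * lrDropFactor^floor((e - 1) / lrDropPeriod)`.
#' @param shuffleSeed seed for the validation split and epoch shuffles.
#' @param validationFraction fraction of patches held out for validation.
#' @param returnBest return the best-validation weights instead of the final.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(maxEpochs = 100L, batchSize = 64L, momentum = 0.9,
                        l2 = 1e-4, gradientThreshold = 0.01,
                        initialLR = 0.1, lrDropFactor = 0.1,
                        lrDropPeriod = 10L, shuffleSeed = 1L,
                        validationFraction = 0.1, returnBest = FALSE) {
  cfg <- new("TrainConfig", maxEpochs = as.integer(maxEpochs),
             batchSize = as.integer(batchSize), momentum = momentum, l2 = l2,
             gradientThreshold = gradientThreshold, initialLR = initialLR,
             lrDropFactor = lrDropFactor, lrDropPeriod = as.integer(lrDropPeriod),
             shuffleSeed = as.integer(shuffleSeed),
             validationFraction = validationFraction, returnBest = returnBest)
  msg <- validObject(cfg, test = TRUE)
  if (is.character(msg)) stopValidation(msg[1])
  cfg
}

#' Desk-scale training profile
#'
#' The package's small-corpus profile for 5-epoch runs over ~200 patches:
#' mini-batch 8 (~135 optimizer steps; mini-batch 64 would allow only ~3
#' steps per epoch at this corpus size), the same x0.1 learning-rate
#' annealing structure compressed to the short run (initial rate 0.01
#' dropping every 2 epochs instead of 0.1 every 10 -- at a few dozen
#' steps the full-scale rate of 0.1 with momentum 0.9 sits at the
#' stability edge of the optimization and makes the outcome a coin flip
#' of the shuffle seed), and best-validation weight selection. Momentum,
#' L2 decay and gradient clipping keep their full-scale defaults.
#'
#' @param shuffleSeed seed for splits and shuffles.
#' @return A \linkS4class{TrainConfig}.
#' @export
deskTrainConfig <- function(shuffleSeed = 1L) {
  trainConfig(maxEpochs = 5L, batchSize = 8L, initialLR = 0.01,
              lrDropPeriod = 2L, shuffleSeed = shuffleSeed,
              returnBest = TRUE)
}

#' Learning rate at a given epoch
#'
#' `initialLR * lrDropFactor^floor((epoch - 1) / lrDropPeriod)`: 0.1 for
#' epochs 1-10, 0.01 for 11-20, 0.001 for 21-30, ... under the defaults.
#'
#' @param config a \linkS4class{TrainConfig}.
#' @param epoch epoch number(s), >= 1.
#' @return Learning rate(s).
#' @export
lrAtEpoch <- function(config, epoch) {
  if (any(epoch < 1)) stopValidation("epoch: must be >= 1")
  config@initialLR * config@lrDropFactor ^ floor((epoch - 1) / config@lrDropPeriod)
}

# Flattened L2 norm across a gradient's weight and bias lists.
gradGlobalNorm <- function(gW, gb) {
  sq <- sum(vapply(gW, function(g) sum(g * g), numeric(1))) +
    sum(vapply(gb, function(g) sum(g * g), numeric(1)))
  sqrt(sq)
}

#' Train a residual network with SGDM
#'
#' Optimizes the model on a \linkS4class{TrainingSet} under the given
#' configuration. A deterministic validation split is drawn first
#' (`validationFraction` of the patches, by `shuffleSeed`); every epoch
#' reshuffles the training patches with a seed derived from `shuffleSeed`
#' and the epoch number. Per batch, the documented update order is
#' decay -> global-norm clip -> momentum -> weight update; biases receive
#' no decay. A non-finite loss aborts with a diagnostic naming epoch and
#' batch.
#'
#' @param dataset a non-empty \linkS4class{TrainingSet}.
#' @param config a \linkS4class{TrainConfig}.
#' @param init initial \linkS4class{VDSRModel} weights.
#' @param verbose print per-epoch progress.
#' @return list(model = trained \linkS4class{VDSRModel},
#'   history = \linkS4class{TrainHistory}).
#' @export
trainVDSR <- function(dataset, config, init, verbose = FALSE) {
  stopifnot(is(dataset, "TrainingSet"), is(config, "TrainConfig"),
            is(init, "VDSRModel"))
  n <- nPairs(dataset)
  if (n < 1L) stopValidation("dataset: must contain at least one pair")

  perm0 <- withSeed(config@shuffleSeed, sample.int(n))
  nVal <- floor(config@validationFraction * n)
  valIdx <- if (nVal > 0) perm0[seq_len(nVal)] else integer(0)
  trainIdx <- if (nVal > 0) perm0[-seq_len(nVal)] else perm0

  W <- lapply(init@weights, `[[`, "W")
  b <- lapply(init@weights, `[[`, "b")
  vW <- lapply(W, function(w) w * 0)
  vb <- lapply(b, function(x) x * 0)

  valLoss <- function() {
    if (!length(valIdx)) return(NA_real_)
    pred <- cpp_vdsr_forward(W, b, dataset@x[, , valIdx, drop = FALSE])
    0.5 * mean((pred - dataset@r[, , valIdx, drop = FALSE])^2)
  }
  initialVal <- valLoss()
  bestVal <- initialVal
  bestW <- W; bestb <- b

  epochRows <- vector("list", config@maxEpochs)
  gradNorms <- numeric(0)
  for (e in seq_len(config@maxEpochs)) {
    lr <- lrAtEpoch(config, e)
    order <- withSeed(deriveSeed(config@shuffleSeed, e),
                      trainIdx[sample.int(length(trainIdx))])
    starts <- seq(1L, length(order), by = config@batchSize)
    batchLosses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- order[starts[bi]:min(starts[bi] + config@batchSize - 1L,
                                  length(order))]
      g <- cpp_vdsr_loss_grad(W, b, dataset@x[, , idx, drop = FALSE],
                              dataset@r[, , idx, drop = FALSE])
      if (!is.finite(g$loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d", e, bi))
      batchLosses[bi] <- g$loss
      gW <- g$gW; gb <- lapply(g$gb, as.vector)
      # (1) L2 decay on weights only
      if (config@l2 > 0)
        for (l in seq_along(gW)) gW[[l]] <- gW[[l]] + config@l2 * W[[l]]
      # (2) global L2-norm clip
      nrm <- gradGlobalNorm(gW, gb)
      if (nrm > config@gradientThreshold) {
        sc <- config@gradientThreshold / nrm
        gW <- lapply(gW, `*`, sc)
        gb <- lapply(gb, `*`, sc)
        nrm <- config@gradientThreshold
      }
      gradNorms <- c(gradNorms, nrm)
      # (3) momentum, (4) update
      for (l in seq_along(W)) {
        vW[[l]] <- config@momentum * vW[[l]] - lr * gW[[l]]
        vb[[l]] <- config@momentum * vb[[l]] - lr * gb[[l]]
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    vl <- valLoss()
    if (length(valIdx) && !is.na(vl) && (is.na(bestVal) || vl < bestVal)) {
      bestVal <- vl; bestW <- W; bestb <- b
    }
    epochRows[[e]] <- data.frame(epoch = e, lr = lr,
                                 trainLoss = mean(batchLosses), valLoss = vl)
    if (verbose)
      message(sprintf("epoch %3d  lr %.4g  train %.6g  val %.6g",
                      e, lr, mean(batchLosses), vl))
  }

  if (config@returnBest && length(valIdx)) { W <- bestW; b <- bestb }
  weights <- lapply(seq_along(W), function(l) list(W = W[[l]], b = b[[l]]))
  model <- new("VDSRModel", depth = init@depth, width = init@width,
               weights = weights, initSeed = init@initSeed)
  history <- new("TrainHistory", epochs = do.call(rbind, epochRows),
                 gradNorms = gradNorms, initialValLoss = initialVal)
  list(model = model, history = history)
}
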