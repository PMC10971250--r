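# Image quality metrics: MSE, PSNR and SSIM. SSIM comes in two modes:
# "global" evaluates the luminance/contrast/structure triple once from
# whole-image moments (the equation-literal reading), "windowed" evaluates
# it per 11x11 Gaussian window (sigma 1.5) and averages the SSIM map --
# the field-standard convention standard toolboxes implement. Moments use the
# population convention (divide by n) in both modes.

#' Construct a metric configuration
#'
#' @param peak maximum possible pixel value R in the PSNR formula: 1 for
#'   \[0, 1\]-normalized grids (the package's working scale), 255 when
#'   operating on 8-bit integer values.
#' @param dynamicRange the L entering C1 = (k1 L)^2, C2 = (k2 L)^2,
#'   C3 = C2/2 (defaults to `peak`).
#' @param k1,k2 SSIM constant factors (0.01 and 0.03).
#' @param alpha,beta,gamma exponents on the luminance, contrast and
#'   structure terms (default 1).
#' @param ssimMode "windowed" (default) or "global".
#' @param windowSize,windowSigma Gaussian window parameters.
#' @return A \linkS4class{MetricConfig}.
#' @export
metricConfig <- function(peak = 1, dynamicRange = peak, k1 = 0.01, k2 = 0.03,
                         alpha = 1, beta = 1, gamma = 1,
                         ssimMode = c("windowed", "global"),
                         windowSize = 11L, windowSigma = 1.5) {
  ssimMode <- match.arg(ssimMode)
  cfg <- new("MetricConfig", peak = peak, dynamicRange = dynamicRange,
             k1 = k1, k2 = k2, alpha = alpha, beta = beta, gamma = gamma,
             ssimMode = ssimMode, windowSize = as.integer(windowSize),
             windowSigma = windowSigma)
  msg <- validObject(cfg, test = TRUE)
  if (is.character(msg)) stopValidation(msg[1])
  cfg
}

asGrid <- function(x) if (is(x, "MRISlice")) pixels(x) else x

#' Mean squared error between two grids
#'
#' @param i1,i2 numeric matrices (or \linkS4class{MRISlice}s) of identical
#'   shape.
#' @return Mean of squared differences.
#' @export
imageMSE <- function(i1, i2) {
  i1 <- asGrid(i1); i2 <- asGrid(i2)
  assertSameShape(i1, i2, "i1 and i2")
  mean((i1 - i2)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(peak^2 / MSE)`. Identical grids (MSE = 0) return `Inf` as a
#' defined sentinel rather than raising an error; tabulating code records
#' this case as a flag.
#'
#' @param i1,i2 grids of identical shape.
#' @param config a \linkS4class{MetricConfig} (only `peak` is used).
#' @return PSNR in decibels.
#' @export
imagePSNR <- function(i1, i2, config = metricConfig()) {
  mse <- imageMSE(i1, i2)
  if (mse == 0) return(Inf)
  10 * log10(config@peak^2 / mse)
}

ssimConstants <- function(config) {
  L <- config@dynamicRange
  C2 <- (config@k2 * L)^2
  list(C1 = (config@k1 * L)^2, C2 = C2, C3 = C2 / 2)
}

# Valid-region Gaussian filtering as a pair of band-matrix products.
gaussianBand <- function(n, size, sigma) {
  half <- (size - 1L) %/% 2L
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g <- g / sum(g)
  nOut <- n - size + 1L
  W <- matrix(0, nOut, n)
  for (i in seq_len(nOut)) W[i, i:(i + size - 1L)] <- g
  W
}

#' Structural similarity index
#'
#' Computes SSIM(A, B) = l^alpha * c^beta * s^gamma with the stabilizing
#' constants C1, C2, C3 = C2/2 derived from the configured dynamic range.
#' Global mode uses one whole-image moment triple; windowed mode evaluates
#' the triple per Gaussian window over the valid interior and averages the
#' resulting SSIM map. The value carries a `components` attribute with the
#' (mean) luminance/contrast/structure terms and moments.
#'
#' @param a,b grids of identical shape (windowed mode requires dims >= the
#'   window size).
#' @param config a \linkS4class{MetricConfig}.
#' @return SSIM value with attribute `components`.
#' @export
imageSSIM <- function(a, b, config = metricConfig()) {
  a <- asGrid(a); b <- asGrid(b)
  assertSameShape(a, b, "a and b")
  k <- ssimConstants(config)
  if (config@ssimMode == "global") {
    muA <- mean(a); muB <- mean(b)
    vA <- mean((a - muA)^2); vB <- mean((b - muB)^2)
    sA <- sqrt(vA); sB <- sqrt(vB)
    sAsB <- sqrt(vA * vB)  # == vA exactly when a == b (IEEE sqrt)
    sAB <- mean((a - muA) * (b - muB))
    l <- (2 * muA * muB + k$C1) / (muA^2 + muB^2 + k$C1)
    cc <- (2 * sAsB + k$C2) / (vA + vB + k$C2)
    s <- (sAB + k$C3) / (sAsB + k$C3)
    val <- l^config@alpha * cc^config@beta * s^config@gamma
    attr(val, "components") <- list(l = l, c = cc, s = s, muA = muA, muB = muB,
                                    sigmaA = sA, sigmaB = sB, sigmaAB = sAB)
    return(val)
  }
  ws <- config@windowSize
  if (any(dim(a) < ws))
    stopValidation("a, b: windowed SSIM requires dims >= ", ws)
  Gr <- gaussianBand(nrow(a), ws, config@windowSigma)
  Gc <- t(gaussianBand(ncol(a), ws, config@windowSigma))
  filt <- function(x) Gr %*% x %*% Gc
  ux <- filt(a); uy <- filt(b)
  vx <- pmax(filt(a * a) - ux^2, 0)
  vy <- pmax(filt(b * b) - uy^2, 0)
  vxy <- filt(a * b) - ux * uy
  sxsy <- sqrt(vx * vy)
  l <- (2 * ux * uy + k$C1) / (ux^2 + uy^2 + k$C1)
  cc <- (2 * sxsy + k$C2) / (vx + vy + k$C2)
  s <- (vxy + k$C3) / (sxsy + k$C3)
  smap <- l^config@alpha * cc^config@beta * s^config@gamma
  val <- mean(smap)
  attr(val, "components") <- list(l = mean(l), c = mean(cc), s = mean(s))
  val
}
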