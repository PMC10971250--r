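# Shared fixture builders. Everything is generated in code from fixed
# seeds or closed forms; the only stored files are frozen oracle outputs
# (reference-resampler and reference-metric values) regenerated against
# inputs rebuilt here.

# Deterministic smooth test images matching the frozen resampler oracles.
resizeFixture64x48 <- function() {
  H <- 64; W <- 48
  i <- matrix(rep(1:H, W), H, W); j <- matrix(rep(1:W, each = H), H, W)
  0.5 + 0.25 * sin(2 * pi * i / 19) * cos(2 * pi * j / 13) +
    0.2 * ((i - 1) / (H - 1)) - 0.1 * ((j - 1) / (W - 1))
}

resizeFixture32x24 <- function() {
  H <- 32; W <- 24
  i <- matrix(rep(1:H, W), H, W); j <- matrix(rep(1:W, each = H), H, W)
  0.5 + 0.3 * sin(2 * pi * i / 11) * cos(2 * pi * j / 7) +
    0.15 * ((j - 1) / (W - 1))
}

# The 50 random 64x64 image pairs behind the frozen reference-metric
# values (metric_oracle.csv). Pair k is the k-th draw under seed 9001.
metricOraclePairs <- function(n = 50) {
  set.seed(9001)
  lapply(seq_len(n), function(k) {
    a <- matrix(runif(64 * 64), 64, 64)
    b <- pmin(pmax(a + matrix(rnorm(64 * 64, 0, 0.05), 64, 64), 0), 1)
    list(a = a, b = b)
  })
}

# Small noiseless phantom for fast structural tests.
quietPhantom <- function(seed = 1, size = 64, sequence = "T2",
                         filament = TRUE) {
  generatePhantom(phantomSpec(seed = seed, size = size, sequence = sequence,
                              noiseSigma = 0, filament = filament))
}

# Tiny training set: patches from small phantoms, used by optimizer tests.
tinyTrainingSet <- function(nSlices = 2, size = 64, patch = 8, seed = 11,
                            scales = 2L) {
  slices <- lapply(seq_len(nSlices), function(i) quietPhantom(seed + i, size))
  buildTrainingSet(slices, scales = scales, nAugment = 0, seed = seed,
                   patchSize = patch, stride = patch)
}

# Independent 2-D convolution oracle: direct nested loops, zero padding.
convOracle <- function(img, kernel3, bias = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      si <- i + di; sj <- j + dj
      v <- if (si >= 1 && si <= H && sj >= 1 && sj <= W) img[si, sj] else 0
      acc <- acc + v * kernel3[di + 2, dj + 2]
    }
    out[i, j] <- acc + bias
  }
  out
}

# Map a 3x3 kernel (indexed kernel[di+2, dj+2] by source offset) to the
# packed single-channel weight column used by VDSRModel.
kernelToColumn <- function(kernel3) {
  w <- numeric(9)
  for (dj in 0:2) for (di in 0:2) w[1 + di + 3 * dj] <- kernel3[di + 1, dj + 1]
  matrix(w, 9, 1)
}
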