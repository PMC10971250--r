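test_that("YCbCr separation and recombination are faithful", {
  s <- quietPhantom(seed = 1, size = 64)
  ycc <- toYCbCr(s)
  expect_identical(ycc@y, pixels(s))
  expect_true(all(ycc@cb == 0.5) && all(ycc@cr == 0.5))
  back <- fromYCbCr(ycc)
  expect_lt(max(abs(pixels(back) - pixels(s))), 1e-6)
  # mid-gray RGB maps to neutral luminance and chrominance
  g <- array(0.5, c(4, 4, 3))
  yg <- toYCbCr(g)
  expect_equal(max(abs(yg@y - 0.5)), 0, tolerance = 1e-9)
  expect_equal(max(abs(yg@cb - 0.5)), 0, tolerance = 1e-9)
  expect_equal(max(abs(yg@cr - 0.5)), 0, tolerance = 1e-9)
  # full 3-channel round trip
  set.seed(12)
  rgb <- array(runif(4 * 4 * 3, 0.1, 0.9), c(4, 4, 3))
  expect_equal(fromYCbCr(toYCbCr(rgb)), rgb, tolerance = 1e-9)
})

test_that("bicubic degradation preserves constants and dimensions", {
  const <- matrix(0.61, 128, 128)
  for (sc in 2:4) {
    x <- degradeSlice(const, sc)
    expect_identical(dim(x), c(128L, 128L))
    expect_lt(max(abs(x - 0.61)), 1e-6)
  }
  # non-divisible case: 256 at scale 3 still returns 256 x 256
  y <- pixels(quietPhantom(seed = 9, size = 256))
  expect_identical(dim(degradeSlice(y, 3)), c(256L, 256L))
  expect_error(degradeSlice(const, 5), class = "mrisr_validation_error")
})

test_that("stronger degradation loses more detail on filament phantoms", {
  for (seed in 1:10) {
    y <- pixels(quietPhantom(seed = seed, size = 128))
    p2 <- imagePSNR(y, degradeSlice(y, 2))
    p4 <- imagePSNR(y, degradeSlice(y, 4))
    expect_lt(p4, p2)
  }
})

test_that("residuals obey their algebraic identities", {
  set.seed(5)
  y <- matrix(runif(64), 8, 8)
  x <- matrix(runif(64), 8, 8)
  r <- residualImage(y, x)
  expect_identical(r, y - x)                     # stored-residual identity
  expect_lt(max(abs((x + r) - y)), 1e-15)        # reconstruction to 1 ulp
  expect_identical(residualImage(y, y), matrix(0, 8, 8))
  expect_identical(residualImage(matrix(0.8, 1, 1), matrix(0.3, 1, 1)),
                   matrix(0.5, 1, 1))
  expect_error(residualImage(y, matrix(0, 4, 4)),
               class = "mrisr_validation_error")
})

test_that("augmentation draws are deterministic and geometrically exact", {
  s <- quietPhantom(seed = 2, size = 64)
  # forced identity draw
  id <- applyAffine(s, 0, 0, 1)
  expect_lt(max(abs(pixels(id) - pixels(s))), 1e-6)
  # same seed, same output
  a1 <- augmentSlice(s, 77); a2 <- augmentSlice(s, 77)
  expect_identical(pixels(a1), pixels(a2))
  expect_identical(dim(pixels(a1)), dim(pixels(s)))
  # pure integer translation moves a delta by exactly (tx, ty)
  delta <- matrix(0, 64, 64); delta[30, 20] <- 1
  moved <- pixels(applyAffine(MRISlice(delta), tx = 5, ty = 0, zoom = 1))
  am <- which(moved == max(moved), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(30, 25))
  moved2 <- pixels(applyAffine(MRISlice(delta), tx = 0, ty = -7, zoom = 1))
  am2 <- which(moved2 == max(moved2), arr.ind = TRUE)
  expect_equal(unname(am2[1, ]), c(23, 20))
})

test_that("patch extraction counts and inherits the residual identity", {
  y <- pixels(quietPhantom(seed = 3, size = 256))
  pair <- mrisr:::residualPair(degradeSlice(y, 2), y, 2)
  ps <- extractPatches(pair, 41, 41)
  expect_length(ps, 36)                       # (floor((256-41)/41)+1)^2 = 36
  for (p in ps[c(1, 18, 36)]) {
    expect_identical(dim(p@x), c(41L, 41L))
    expect_identical(p@r, p@yTrue - p@x)
  }
  # a patch-sized image yields exactly one patch at any stride
  y41 <- y[1:41, 1:41]
  pair41 <- mrisr:::residualPair(degradeSlice(y41, 2), y41, 2)
  expect_length(extractPatches(pair41, 41, 13), 1)
  expect_error(extractPatches(pair41, 64), class = "mrisr_validation_error")
})

test_that("training sets pool patches multiplicatively over scales", {
  s <- quietPhantom(seed = 4, size = 256)
  t1 <- buildTrainingSet(list(s), scales = 2L, seed = 1)
  expect_equal(nPairs(t1), 36)
  t3 <- buildTrainingSet(list(s), scales = c(2L, 3L, 4L), seed = 1)
  expect_equal(nPairs(t3), 108)
  expect_setequal(unique(t3@scale), 2:4)
})

test_that("training-set construction is reproducible and identity-preserving", {
  slices <- lapply(1:2, function(i) quietPhantom(seed = i, size = 64))
  a <- buildTrainingSet(slices, scales = 2L, nAugment = 2, seed = 99,
                        patchSize = 16, stride = 16)
  b <- buildTrainingSet(slices, scales = 2L, nAugment = 2, seed = 99,
                        patchSize = 16, stride = 16)
  expect_identical(a@manifest, b@manifest)
  expect_identical(a@x, b@x)
  expect_identical(a@r, b@r)
  # residual identity over 100% of stored pairs
  expect_identical(a@r, a@yTrue - a@x)
  # augmentation grows the pool: (1 + 2 augments) * 16 patches * 2 slices
  expect_equal(nPairs(a), 3 * 16 * 2)
})

test_that("training sets round-trip through the on-disk layout", {
  ts <- tinyTrainingSet()
  d <- withr::local_tempdir()
  writeTrainingSet(ts, d)
  back <- readTrainingSet(d)
  expect_identical(back@x, ts@x)
  expect_identical(back@yTrue, ts@yTrue)
  expect_identical(back@r, ts@r)
  expect_identical(back@scale, ts@scale)
  expect_equal(back@manifest$slice_id, ts@manifest$slice_id)
  expect_error(readTrainingSet(file.path(d, "nope")),
               class = "mrisr_format_error")
})
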