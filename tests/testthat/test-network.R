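test_that("initialization is deterministic and has the documented shape", {
  m1 <- initVDSR(depth = 5, width = 8, seed = 13)
  m2 <- initVDSR(depth = 5, width = 8, seed = 13)
  expect_identical(m1@weights, m2@weights)
  m3 <- initVDSR(depth = 5, width = 8, seed = 14)
  expect_false(identical(m1@weights, m3@weights))
  # layer map 1 -> width -> ... -> width -> 1
  expect_equal(dim(m1@weights[[1]]$W), c(9, 8))
  expect_equal(dim(m1@weights[[3]]$W), c(72, 8))
  expect_equal(dim(m1@weights[[5]]$W), c(72, 1))
  # the reconstruction layer starts at zero: untrained residual is null
  expect_true(all(m1@weights[[5]]$W == 0))
})

test_that("parameter counts match the closed-form layer map", {
  # (3*3*1*64 + 64) + 18*(3*3*64*64 + 64) + (3*3*64*1 + 1)
  expect_equal(nParams(initVDSR(20, 64, 1)), 665921)
  expect_equal(nParams(initVDSR(2, 1, 1)), 20)   # (9+1) + (9+1)
})

test_that("an all-zero network maps every input to zero", {
  m <- initVDSR(depth = 3, width = 2, seed = 1)
  for (l in 1:3) m@weights[[l]]$W[] <- 0
  set.seed(2)
  x <- matrix(runif(64), 8, 8)
  expect_true(all(vdsrForward(m, x) == 0))
})

test_that("forward pass preserves spatial dimensions (padding contract)", {
  m <- initVDSR(depth = 4, width = 3, seed = 5)
  m@weights[[4]]$W[] <- rnorm(27, sd = 0.1)      # make output non-trivial
  for (d in list(c(41L, 41L), c(64L, 64L), c(50L, 70L))) {
    x <- matrix(runif(prod(d)), d[1], d[2])
    expect_identical(dim(vdsrForward(m, x)), d)
  }
  # batch input: H x W x N in, H x W x N out
  xb <- array(runif(41 * 41 * 3), c(41, 41, 3))
  expect_identical(dim(vdsrForward(m, xb)), c(41L, 41L, 3L))
  expect_error(vdsrForward(m, 1:5), class = "mrisr_validation_error")
})

test_that("a depth-2 network reproduces a hand-computed conv+ReLU trace", {
  set.seed(31)
  k1 <- matrix(rnorm(9, sd = 0.4), 3, 3)
  k2 <- matrix(rnorm(9, sd = 0.4), 3, 3)
  b1 <- 0.05; b2 <- -0.02
  m <- initVDSR(depth = 2, width = 1, seed = 1)
  m@weights[[1]]$W <- kernelToColumn(k1); m@weights[[1]]$b <- b1
  m@weights[[2]]$W <- kernelToColumn(k2); m@weights[[2]]$b <- b2
  x <- matrix(runif(9), 3, 3)
  expected <- convOracle(pmax(convOracle(x, k1, b1), 0), k2, b2)
  expect_equal(vdsrForward(m, x), expected, tolerance = 1e-12)
  # identity kernel (centre tap 1) with zero bias passes ReLU-positive input
  idk <- matrix(0, 3, 3); idk[2, 2] <- 1
  m@weights[[1]]$W <- kernelToColumn(idk); m@weights[[1]]$b <- 0
  m@weights[[2]]$W <- kernelToColumn(idk); m@weights[[2]]$b <- 0
  expect_equal(vdsrForward(m, x), x, tolerance = 1e-14)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  m <- initVDSR(depth = 3, width = 2, seed = 7)
  m@weights[[3]]$W <- matrix(rnorm(18, sd = 0.3), 18, 1)
  m@weights[[3]]$b <- 0.05
  x <- array(runif(25), c(5, 5, 1))
  r <- array(runif(25, -0.1, 0.1), c(5, 5, 1))
  g <- vdsrLossGrad(m, x, r)
  eps <- 1e-6
  for (l in 1:3) {
    W <- m@weights[[l]]$W
    for (k in sample(length(W), min(6, length(W)))) {
      mp <- m; mp@weights[[l]]$W[k] <- W[k] + eps
      mm <- m; mm@weights[[l]]$W[k] <- W[k] - eps
      num <- (vdsrLossGrad(mp, x, r)$loss - vdsrLossGrad(mm, x, r)$loss) /
        (2 * eps)
      an <- g$gW[[l]][k]
      expect_lt(abs(num - an) / max(abs(num), abs(an), 1e-8), 1e-4)
    }
    bp <- m; bp@weights[[l]]$b[1] <- m@weights[[l]]$b[1] + eps
    bm <- m; bm@weights[[l]]$b[1] <- m@weights[[l]]$b[1] - eps
    num <- (vdsrLossGrad(bp, x, r)$loss - vdsrLossGrad(bm, x, r)$loss) /
      (2 * eps)
    expect_lt(abs(num - g$gb[[l]][1]) / max(abs(num), 1e-8), 1e-4)
  }
})

test_that("the loss is half the mean squared residual error", {
  expect_identical(vdsrLoss(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  # r = [1, 0], pred = [0, 0]: 0.5 * (1 + 0) / 2 = 0.25
  expect_identical(vdsrLoss(matrix(c(0, 0), 1, 2), matrix(c(1, 0), 1, 2)), 0.25)
  set.seed(6)
  a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
  expect_identical(vdsrLoss(a, b), vdsrLoss(b, a))
  expect_error(vdsrLoss(a, matrix(0, 2, 2)), class = "mrisr_validation_error")
})

test_that("checkpoints round-trip and detect corruption", {
  m <- initVDSR(depth = 3, width = 4, seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  h <- writeCheckpoint(m, f, provenance = list(note = "unit test"))
  back <- readCheckpoint(f)
  expect_identical(back@weights, m@weights)
  expect_identical(modelHash(back), h)
  # tamper with a stored weight -> hash mismatch
  obj <- readRDS(f)
  obj$weights[[1]]$W[1] <- obj$weights[[1]]$W[1] + 1
  saveRDS(obj, f)
  expect_error(readCheckpoint(f), class = "mrisr_format_error")
  g <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(junk = 1), g)
  expect_error(readCheckpoint(g), class = "mrisr_format_error")
})
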