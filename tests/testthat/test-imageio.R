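test_that("DICOM reading maps stored values through the fixed window", {
  f <- withr::local_tempfile(fileext = ".dcm")
  m <- matrix(1234L, 16, 16)
  writeTestDicom(f, m, bits = 16L, spacing = 0.5)
  s <- readDicomSlice(f, window = c(0, 4095))
  expect_s4_class(s, "MRISlice")
  expect_equal(dim(pixels(s)), c(16, 16))
  expect_equal(unique(as.vector(pixels(s))), 1234 / 4095, tolerance = 1e-12)
  expect_equal(spacing(s), 0.5)
  expect_equal(s@bitDepthSource, 16L)
})

test_that("RescaleSlope/Intercept are applied before normalization", {
  f <- withr::local_tempfile(fileext = ".dcm")
  stored <- matrix(c(0L, 1000L, 2000L, 4095L), 2, 2, byrow = TRUE)
  writeTestDicom(f, stored, bits = 16L, slope = 2, intercept = -1024)
  s <- readDicomSlice(f)
  # manual two-step oracle: rescale then min-max to [0, 1]
  resc <- stored * 2 - 1024
  expected <- (resc - min(resc)) / (max(resc) - min(resc))
  expect_equal(pixels(s), expected, tolerance = 1e-12)
})

test_that("implicit-VR little endian files are read too", {
  f <- withr::local_tempfile(fileext = ".dcm")
  m <- matrix(seq(0L, 255L), 16, 16)
  writeTestDicom(f, m, bits = 16L, explicit = FALSE)
  s <- readDicomSlice(f, window = c(0, 255))
  expect_equal(pixels(s), m / 255, tolerance = 1e-12)
})

test_that("non-DICOM, truncated and compressed inputs raise format errors", {
  bad <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(sample(0:255, 200, replace = TRUE)), bad)
  expect_error(readDicomSlice(bad), class = "mrisr_format_error")

  tr <- withr::local_tempfile(fileext = ".dcm")
  writeTestDicom(tr, matrix(7L, 32, 32), bits = 16L)
  raw <- readBin(tr, "raw", file.size(tr))
  writeBin(raw[1:(length(raw) - 600)], tr)       # chop pixel data
  expect_error(readDicomSlice(tr), class = "mrisr_format_error")

  cx <- withr::local_tempfile(fileext = ".dcm")
  writeTestDicom(cx, matrix(7L, 8, 8), bits = 16L,
                 transferSyntax = "1.2.840.10008.1.2.4.70")  # JPEG lossless
  expect_error(readDicomSlice(cx), class = "mrisr_format_error")
})

test_that("8-bit quantization rounds half up and is idempotent", {
  s <- MRISlice(matrix(c(0, 1, 0.5, 0.25), 2, 2))
  q <- to8bit(s)
  expect_identical(pixels(q)[1, 1], 0)
  expect_identical(pixels(q)[2, 1], 1)
  expect_identical(pixels(q)[1, 2], 128 / 255)   # round(127.5) = 128, half-up
  q2 <- to8bit(q)
  expect_identical(pixels(q2), pixels(q))
  set.seed(3)
  r <- MRISlice(matrix(runif(256), 16, 16))
  expect_identical(pixels(to8bit(to8bit(r))), pixels(to8bit(r)))
})

test_that("bicubic resize honours its contracts", {
  const <- MRISlice(matrix(0.37, 40, 40))
  out <- resizeSlice(const, 23)
  expect_equal(dim(pixels(out)), c(23, 23))
  expect_lt(max(abs(pixels(out) - 0.37)), 1e-6)
  set.seed(8)
  img <- MRISlice(matrix(runif(40 * 40), 40, 40))
  same <- resizeSlice(img, 40)
  expect_lt(max(abs(pixels(same) - pixels(img))), 1e-6)
  expect_error(resizeSlice(img, 1), class = "mrisr_validation_error")
})

test_that("resampling matches the frozen reference-resampler outputs", {
  down <- mrisr:::resampleGrid(resizeFixture64x48(), c(32, 24))
  oracleDown <- as.matrix(read.table(test_path("resize_down_32x24.txt")))
  dimnames(oracleDown) <- NULL
  expect_lt(max(abs(down - oracleDown)), 1e-3)
  up <- mrisr:::resampleGrid(resizeFixture32x24(), c(48, 36))
  oracleUp <- as.matrix(read.table(test_path("resize_up_48x36.txt")))
  dimnames(oracleUp) <- NULL
  expect_lt(max(abs(up - oracleUp)), 1e-3)
})

test_that("PNG round-trip is lossless at 8 bits", {
  s <- quietPhantom(seed = 2, size = 64)
  f <- withr::local_tempfile(fileext = ".png")
  writeSliceImage(s, f, "png")
  back <- readSliceImage(f)
  expect_identical(pixels(back), pixels(to8bit(s)))
})

test_that("JPEG at quality 100 keeps PSNR at or above 40 dB", {
  s <- quietPhantom(seed = 3, size = 64)
  f <- withr::local_tempfile(fileext = ".jpg")
  writeSliceImage(s, f, "jpeg", quality = 100)
  back <- readSliceImage(f)
  expect_gte(imagePSNR(pixels(to8bit(s)), pixels(back)), 40)
})

test_that("truncated image files raise a format error", {
  s <- quietPhantom(seed = 4, size = 64)
  f <- withr::local_tempfile(fileext = ".png")
  writeSliceImage(s, f, "png")
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:40], f)
  expect_error(readSliceImage(f), class = "mrisr_format_error")
})
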