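test_that("paired evaluation produces two records per slice per scale", {
  m <- initVDSR(depth = 3, width = 4, seed = 1)   # zero residual branch
  slices <- lapply(1:3, function(i) quietPhantom(seed = i, size = 64))
  rec <- evaluatePairs(slices, m, scales = c(2L, 3L))
  expect_equal(nrow(rec), 2 * 3 * 2)
  expect_setequal(unique(rec$method), c("bicubic", "sr"))
  # with a zero network, bicubic and SR records are identical per slice
  for (id in unique(rec$image_id)) for (sc in c(2L, 3L)) {
    rb <- rec[rec$image_id == id & rec$scale == sc & rec$method == "bicubic", ]
    rs <- rec[rec$image_id == id & rec$scale == sc & rec$method == "sr", ]
    expect_identical(rb$mse, rs$mse)
    expect_identical(rb$psnr_db, rs$psnr_db)
    expect_identical(rb$ssim, rs$ssim)
  }
})

test_that("perfect-SSIM pairs are excluded pairwise", {
  m <- initVDSR(depth = 3, width = 4, seed = 2)
  flat <- MRISlice(matrix(0.5, 64, 64), id = "flat")     # lossless degrade
  tex <- quietPhantom(seed = 4, size = 64)
  rec <- evaluatePairs(list(flat, tex), m, scales = 2L)
  filt <- suppressMessages(excludePerfect(rec))
  expect_false("flat" %in% filt$image_id)                # both rows removed
  expect_true(all(filt$image_id == sliceId(tex)))
  expect_equal(nrow(filt), 2)
  # nothing perfect -> identity
  filt2 <- excludePerfect(filt)
  expect_identical(filt2$ssim, filt$ssim)
})

test_that("the internal paired t-test matches textbook and reference values", {
  r <- pairedTTest(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r$statistic, -4, tolerance = 1e-12)
  expect_equal(r$p.value, 2 * pt(-4, 2), tolerance = 1e-12)
  expect_equal(r$p.value, 0.0572, tolerance = 1e-3)
  set.seed(81)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    ref <- stats::t.test(x, y, paired = TRUE)
    mine <- pairedTTest(x, y)
    expect_lt(abs(mine$statistic - unname(ref$statistic)), 1e-10)
    expect_lt(abs(mine$p.value - ref$p.value), 1e-10)
  }
  # degenerate: identical vectors flagged, not an error
  dg <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_true(dg$degenerate)
  expect_identical(dg$statistic, 0)
  expect_identical(dg$p.value, 1)
  expect_error(pairedTTest(1, 1), class = "mrisr_validation_error")
})

test_that("the summary table aggregates exactly and keeps one row per scale", {
  m <- initVDSR(depth = 3, width = 4, seed = 3)
  slices <- lapply(1:4, function(i) quietPhantom(seed = i, size = 64))
  rec <- evaluatePairs(slices, m, scales = c(2L, 3L, 4L))
  tab <- summarizeEval(rec)
  expect_equal(nrow(tab), 3)
  expect_identical(tab$scale, c(2L, 3L, 4L))
  # spreadsheet-style re-aggregation oracle
  for (i in seq_len(3)) {
    sub <- rec[rec$scale == tab$scale[i] & rec$method == "bicubic", ]
    expect_identical(tab$psnr_bicubic[i], mean(sub$psnr_db))
    expect_identical(tab$ssim_bicubic[i], mean(sub$ssim))
    expect_equal(tab$n_images[i], 4)
  }
  # identical methods (zero network) -> degenerate paired tests, p = 1
  expect_true(all(tab$p_psnr == 1))
  # single image: means without p-values, with a warning
  solo <- rec[rec$image_id == rec$image_id[1] & rec$scale == 2L, ]
  expect_warning(one <- summarizeEval(solo), "fewer than 2")
  expect_true(all(is.na(one$p_psnr)))
  # CSV rendering round-trips
  f <- withr::local_tempfile(fileext = ".csv")
  summarizeEval(rec, csv = f)
  expect_equal(nrow(read.csv(f)), 3)
})

test_that("fiducial localization is symmetric and self-consistent", {
  flat <- MRISlice(matrix(0.1, 96, 96), spacing = 0.8, id = "bg")
  # grid-aligned centre: the half-max region is exactly symmetric, so the
  # centroid recovers the true position to numerical precision
  aligned <- targetCoordinate(40, 57, spacing = 0.8)
  locA <- localizeTarget(embedFiducial(flat, aligned, 0.6, 1.6), aligned)
  expect_lt(abs(locA@x - 40), 1e-3)
  expect_lt(abs(locA@y - 57), 1e-3)
  # arbitrary sub-pixel centre: accuracy is limited by the hard half-max
  # truncation on the pixel grid; well under a tenth of a pixel
  co <- targetCoordinate(40.4, 57.8, spacing = 0.8)
  s <- embedFiducial(flat, co, amplitude = 0.6, sigma = 1.6)
  loc <- localizeTarget(s, co)
  expect_lt(abs(loc@x - 40.4), 0.05)
  expect_lt(abs(loc@y - 57.8), 0.05)
  chk <- coordinateCheck(s, s, co, tolerancePx = 0.5)
  expect_identical(chk$shift_px, 0)
  expect_true(chk$pass)
  expect_equal(chk$shift_mm, 0)
  expect_error(localizeTarget(MRISlice(matrix(0, 64, 64)),
                              targetCoordinate(32, 32)),
               class = "mrisr_validation_error")
})

test_that("texture surfaces enumerate the full pixel lattice", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  surf <- textureSurface(MRISlice(m))
  expect_equal(nrow(surf), 4)
  expect_equal(surf$intensity[surf$x == 1 & surf$y == 2], 0.2)
  expect_equal(surf$intensity[surf$x == 2 & surf$y == 1], 0.3)
  big <- textureSurface(quietPhantom(seed = 5, size = 64))
  expect_equal(nrow(big), 64 * 64)
})
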