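# The paired evaluation design: bicubic restoration vs. super-resolution
# across scale factors, exclusion of degenerate (SSIM = 1) pairs, an
# internally implemented paired t-test, the per-scale summary table, the
# fiducial coordinate-invariance check and the 3-D texture export.

#' Evaluate bicubic vs. super-resolution over a slice set
#'
#' For each ground-truth slice and each scale: degrade the luminance
#' bicubically, restore it (a) by the bicubic upsampling itself and (b) by
#' the network, and score both restorations against the ground truth with
#' PSNR and SSIM. Produces two quality records per slice per scale.
#'
#' @param gtSlices list of ground-truth \linkS4class{MRISlice}s.
#' @param model a trained \linkS4class{VDSRModel}.
#' @param scales integer scales to evaluate (subset of c(2, 3, 4)).
#' @param config a \linkS4class{MetricConfig}.
#' @return data.frame of quality records with columns image_id, scale,
#'   method ("bicubic"/"sr"), mse, psnr_db, ssim, psnr_infinite, ssim_mode.
#' @export
evaluatePairs <- function(gtSlices, model, scales = c(2L, 3L, 4L),
                          config = metricConfig()) {
  stopifnot(is(model, "VDSRModel"))
  if (length(gtSlices) == 0L) stopValidation("gtSlices: at least one required")
  rows <- list()
  for (s in gtSlices) {
    y <- pixels(s)
    for (sc in scales) {
      x <- degradeSlice(y, sc)
      sr <- superResolve(model, MRISlice(x, bitDepthSource = s@bitDepthSource,
                                         spacing = s@spacing,
                                         seqTag = s@seqTag, id = s@id),
                         sc, upsampled = TRUE)
      for (m in c("bicubic", "sr")) {
        rec <- if (m == "bicubic") x else pixels(sr)
        mse <- imageMSE(y, rec)
        psnr <- imagePSNR(y, rec, config)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = sliceId(s), scale = as.integer(sc), method = m,
          mse = mse, psnr_db = if (is.finite(psnr)) psnr else NA_real_,
          ssim = as.numeric(imageSSIM(y, rec, config)),
          psnr_infinite = !is.finite(psnr), ssim_mode = config@ssimMode,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Exclude degenerate (SSIM = 1) image/scale pairs
#'
#' Removes, pairwise, both method records of any (image, scale) whose SSIM
#' equals 1 within `tol` for either method -- such pairs carry no
#' information about restoration quality. Exclusions are reported via a
#' message and an "excluded" attribute.
#'
#' @param records data.frame from \code{\link{evaluatePairs}}.
#' @param tol closeness to 1 that counts as perfect (default 1e-12).
#' @return The filtered records.
#' @export
excludePerfect <- function(records, tol = 1e-12) {
  key <- paste(records$image_id, records$scale)
  bad <- unique(key[records$ssim >= 1 - tol])
  out <- records[!key %in% bad, , drop = FALSE]
  if (length(bad))
    message(sprintf("excluded %d image/scale pair(s) with SSIM = 1", length(bad)))
  attr(out, "excluded") <- bad
  out
}

#' Paired t-test
#'
#' Classical paired t on the differences x - y with a two-sided p-value
#' from Student's t with n - 1 degrees of freedom. Implemented internally
#' so the statistics path is itself under test; agreement with
#' `stats::t.test(paired = TRUE)` is asserted in the test suite.
#' Zero-variance differences are flagged degenerate instead of erroring:
#' t = 0, p = 1 when the mean difference is also zero, otherwise an
#' infinite statistic with p = 0.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list(statistic, df, p.value, meanDiff, degenerate).
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stopValidation("x, y: must have equal length")
  n <- length(x)
  if (n < 2L) stopValidation("x, y: need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    return(list(statistic = if (md == 0) 0 else sign(md) * Inf,
                df = n - 1L, p.value = if (md == 0) 1 else 0,
                meanDiff = md, degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  list(statistic = t, df = n - 1L, p.value = 2 * pt(-abs(t), n - 1L),
       meanDiff = md, degenerate = FALSE)
}

#' Summarize quality records into the per-scale comparison table
#'
#' One row per scale: record count after exclusion, mean PSNR and SSIM for
#' bicubic and SR, and the paired (by image) two-sided t statistics and
#' p-values for PSNR and SSIM. Raw p-values are reported (no
#' multiple-testing adjustment across scales, matching the evaluation
#' design the table mirrors). With fewer than 2 images at a scale the
#' means are emitted without p-values and a warning is logged.
#'
#' @param records (exclusion-filtered) data.frame from
#'   \code{\link{evaluatePairs}}.
#' @param csv optional path; when given the table is also written as CSV.
#' @return data.frame with columns scale, n_images, psnr_bicubic, psnr_sr,
#'   ssim_bicubic, ssim_sr, t_psnr, p_psnr, t_ssim, p_ssim.
#' @export
summarizeEval <- function(records, csv = NULL) {
  rows <- lapply(sort(unique(records$scale)), function(sc) {
    rb <- records[records$scale == sc & records$method == "bicubic", ]
    rs <- records[records$scale == sc & records$method == "sr", ]
    rb <- rb[order(rb$image_id), ]; rs <- rs[order(rs$image_id), ]
    n <- nrow(rb)
    out <- data.frame(scale = sc, n_images = n,
                      psnr_bicubic = mean(rb$psnr_db),
                      psnr_sr = mean(rs$psnr_db),
                      ssim_bicubic = mean(rb$ssim), ssim_sr = mean(rs$ssim),
                      t_psnr = NA_real_, p_psnr = NA_real_,
                      t_ssim = NA_real_, p_ssim = NA_real_)
    if (n >= 2L) {
      tp <- pairedTTest(rs$psnr_db, rb$psnr_db)
      ts <- pairedTTest(rs$ssim, rb$ssim)
      out$t_psnr <- tp$statistic; out$p_psnr <- tp$p.value
      out$t_ssim <- ts$statistic; out$p_ssim <- ts$p.value
    } else {
      warning(sprintf("scale %d: fewer than 2 images; no paired test", sc))
    }
    out
  })
  tab <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  tab
}

#' Localize a point target by half-max region centroid
#'
#' Within a square search window centred on the nominal coordinate, finds
#' the local maximum, keeps the 4-connected region around it whose
#' intensities exceed half that maximum, and returns the centroid weighted
#' by intensity above that threshold (background-offset free, so a
#' symmetric peak localizes to its true sub-pixel centre). A deterministic
#' stand-in for manual target verification.
#'
#' @param slice an \linkS4class{MRISlice} (or matrix).
#' @param nominal a \linkS4class{TargetCoordinate} centring the window.
#' @param searchRadius half-width of the search window in px.
#' @return A \linkS4class{TargetCoordinate}.
#' @export
localizeTarget <- function(slice, nominal, searchRadius = 10L) {
  p <- asGrid(slice)
  rr <- max(1L, round(nominal@y) - searchRadius):
    min(nrow(p), round(nominal@y) + searchRadius)
  cc <- max(1L, round(nominal@x) - searchRadius):
    min(ncol(p), round(nominal@x) + searchRadius)
  w <- p[rr, cc, drop = FALSE]
  mx <- max(w)
  if (mx <= 0) stopValidation("localization failure: no signal in window")
  thr <- mx / 2
  seed <- which(w == mx, arr.ind = TRUE)[1, ]
  above <- w >= thr
  # BFS flood fill (4-connectivity) from the maximum
  keep <- matrix(FALSE, nrow(w), ncol(w))
  queue <- list(c(seed[1], seed[2]))
  keep[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    q <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      i <- q[1] + d[1]; j <- q[2] + d[2]
      if (i >= 1 && i <= nrow(w) && j >= 1 && j <= ncol(w) &&
          above[i, j] && !keep[i, j]) {
        keep[i, j] <- TRUE
        queue[[length(queue) + 1L]] <- c(i, j)
      }
    }
  }
  # weight by height above the threshold: removes the flat background
  # offset, so a symmetric peak localizes to its true sub-pixel centre
  wts <- ifelse(keep, w - thr, 0)
  tot <- sum(wts)
  if (tot <= 0) stopValidation("localization failure: empty half-max region")
  ci <- sum(row(w) * wts) / tot
  cj <- sum(col(w) * wts) / tot
  targetCoordinate(x = cc[1] - 1 + cj, y = rr[1] - 1 + ci,
                   spacing = if (is(slice, "MRISlice")) slice@spacing
                             else NA_real_)
}

#' Coordinate-invariance check for a fiducial target
#'
#' Localizes the fiducial independently in the ground-truth and the
#' reconstructed slice (see \code{\link{localizeTarget}}) and reports the
#' Euclidean shift between the two localizations, its millimetre
#' equivalent when spacing is known, and pass/fail at the tolerance
#' (default 0.5 px: a sub-pixel shift is "no difference" at image
#' resolution).
#'
#' @param gt,sr ground-truth and reconstructed \linkS4class{MRISlice}s.
#' @param trueCoord nominal \linkS4class{TargetCoordinate}.
#' @param tolerancePx pass threshold in pixels (> 0).
#' @param searchRadius search window half-width in px.
#' @return One-row data.frame: true_x, true_y, gt_x, gt_y, sr_x, sr_y,
#'   shift_px, shift_mm (NA without spacing), pass.
#' @export
coordinateCheck <- function(gt, sr, trueCoord, tolerancePx = 0.5,
                            searchRadius = 10L) {
  if (tolerancePx <= 0) stopValidation("tolerancePx: must be > 0")
  g <- localizeTarget(gt, trueCoord, searchRadius)
  r <- localizeTarget(sr, trueCoord, searchRadius)
  shift <- sqrt((g@x - r@x)^2 + (g@y - r@y)^2)
  sp <- spacing(gt)
  data.frame(true_x = trueCoord@x, true_y = trueCoord@y,
             gt_x = g@x, gt_y = g@y, sr_x = r@x, sr_y = r@y,
             shift_px = shift,
             shift_mm = if (is.na(sp)) NA_real_ else shift * sp,
             pass = shift <= tolerancePx)
}

#' Export a slice as a 3-D pixel-composition point set
#'
#' The full pixel lattice as (x, y, intensity) triples, for side-by-side
#' texture-surface comparison of ground truth and reconstruction.
#'
#' @param slice an \linkS4class{MRISlice}.
#' @return data.frame with H*W rows and columns x, y, intensity.
#' @export
textureSurface <- function(slice) {
  p <- asGrid(slice)
  data.frame(x = as.vector(col(p)), y = as.vector(row(p)),
             intensity = as.vector(p))
}
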