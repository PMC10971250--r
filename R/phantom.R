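# Synthetic MRI-like phantoms: an elliptical "head" with nested tissue
# regions whose mean intensities follow per-sequence presets, an optional
# thin anti-aliased filament (trigeminal-nerve analog), optional Gaussian
# fiducial targets, and Rician noise (the magnitude-image noise law of MRI).

# Per-sequence tissue intensity presets. Invented contrasts, chosen so the
# five tags are visually distinct and plausible (e.g. bright CSF on
# T2-weighted and VISTA, dark CSF on T1-weighted); no physical signal model.
sequencePresets <- list(
  T2    = c(background = 0.00, scalp = 0.35, wm = 0.40, gm = 0.50, csf = 0.95),
  T1    = c(background = 0.00, scalp = 0.60, wm = 0.70, gm = 0.55, csf = 0.10),
  CET1  = c(background = 0.00, scalp = 0.62, wm = 0.68, gm = 0.56, csf = 0.12),
  VISTA = c(background = 0.00, scalp = 0.30, wm = 0.45, gm = 0.55, csf = 0.90),
  PD    = c(background = 0.00, scalp = 0.50, wm = 0.60, gm = 0.70, csf = 0.80)
)

# Filament intensity presets: dark against the bright cisternal CSF on
# T2-like contrasts, bright on T1-like ones -- always high-contrast against
# the tissue it crosses.
filamentIntensity <- c(T2 = 0.15, T1 = 0.92, CET1 = 0.95, VISTA = 0.15,
                       PD = 0.25)

# Default filament: a gently curved three-segment polyline crossing the
# deep-grey region, in coordinates relative to the image size.
defaultFilamentPoints <- matrix(c(
  0.50, 0.55,
  0.42, 0.52,
  0.35, 0.50,
  0.28, 0.46), ncol = 2, byrow = TRUE)

#' Construct a PhantomSpec
#'
#' @param seed integer RNG seed; the same spec regenerates a bit-identical
#'   slice.
#' @param size pixels per side (default 256).
#' @param sequence sequence preset tag: "T2", "T1", "CET1", "VISTA" or "PD".
#' @param tissueLevels named numeric vector (background, scalp, wm, gm, csf)
#'   in \[0, 1\]; defaults to the sequence preset.
#' @param noiseSigma Rician noise scale (default 0.015 intensity units).
#' @param filament TRUE for the default trigeminal-nerve analog, FALSE for
#'   none, or a list(points, width, intensity) with points a k x 2 matrix of
#'   (x, y) pixel coordinates.
#' @param fiducial NULL for none, or a list(x, y, amplitude, sigma) Gaussian
#'   point target.
#' @param geometryScale multiplier on all region radii in \[0.8, 1.2\].
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(seed = 7, sequence = "T2")
#' slice <- generatePhantom(spec)
#' @export
phantomSpec <- function(seed = 1L, size = 256L, sequence = "T2",
                        tissueLevels = NULL, noiseSigma = 0.015,
                        filament = TRUE, fiducial = NULL,
                        geometryScale = 1) {
  if (is.null(tissueLevels)) {
    if (!sequence %in% names(sequencePresets))
      stopValidation("sequence: must be one of ",
                     paste(names(sequencePresets), collapse = ", "))
    tissueLevels <- sequencePresets[[sequence]]
  }
  fil <- if (isTRUE(filament)) {
    list(points = defaultFilamentPoints * size, width = 1.8,
         intensity = unname(filamentIntensity[sequence]))
  } else if (isFALSE(filament) || is.null(filament)) list() else filament
  fid <- if (is.null(fiducial)) list() else fiducial
  sp <- new("PhantomSpec", seed = as.integer(seed), size = as.integer(size),
            sequence = sequence, tissueLevels = tissueLevels,
            noiseSigma = as.numeric(noiseSigma),
            geometryScale = as.numeric(geometryScale),
            filament = fil, fiducial = fid)
  msg <- validObject(sp, test = TRUE)
  if (is.character(msg)) stopValidation(msg[1])
  sp
}

# Nested elliptical region masks (relative semi-axes before geometryScale).
phantomRegions <- function(n, gs) {
  c0 <- (n + 1) / 2
  X <- matrix(rep(seq_len(n), each = n), n, n)   # column index = x
  Y <- matrix(rep(seq_len(n), n), n, n)          # row index = y
  ell <- function(rx, ry) ((X - c0) / (rx * n * gs))^2 +
    ((Y - c0) / (ry * n * gs))^2 <= 1
  list(scalp = ell(0.40, 0.46), wm = ell(0.34, 0.40),
       gm = ell(0.16, 0.20), csf = ell(0.06, 0.11))
}

#' Generate a synthetic phantom slice
#'
#' Renders the nested tissue regions at their exact preset levels
#' (boundaries are hard so the noiseless image is piecewise constant),
#' draws the filament with anti-aliased coverage blending, adds the
#' fiducial bump if present, then applies Rician noise
#' \eqn{|signal + n_1 + i n_2|} with \eqn{n_k \sim N(0, \sigma)} under the
#' spec's seed. The result is clipped to \[0, 1\].
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return An \linkS4class{MRISlice} (id "phantom-<seed>").
#' @export
generatePhantom <- function(spec) {
  msg <- validObject(spec, test = TRUE)
  if (is.character(msg)) stopValidation(msg[1])
  n <- spec@size
  tl <- spec@tissueLevels
  regions <- phantomRegions(n, spec@geometryScale)
  img <- matrix(tl[["background"]], n, n)
  img[regions$scalp] <- tl[["scalp"]]
  img[regions$wm] <- tl[["wm"]]
  img[regions$gm] <- tl[["gm"]]
  img[regions$csf] <- tl[["csf"]]

  if (length(spec@filament))
    img <- drawFilament(img, spec@filament$points, spec@filament$width,
                        spec@filament$intensity)
  if (length(spec@fiducial)) {
    fd <- spec@fiducial
    img <- addGaussianBump(img, fd$x, fd$y, fd$amplitude, fd$sigma)
  }
  if (spec@noiseSigma > 0) {
    img <- withSeed(spec@seed, {
      n1 <- matrix(rnorm(n * n, 0, spec@noiseSigma), n, n)
      n2 <- matrix(rnorm(n * n, 0, spec@noiseSigma), n, n)
      sqrt((img + n1)^2 + n2^2)
    })
  }
  MRISlice(clip01(img), bitDepthSource = 8L, spacing = NA_real_,
           seqTag = spec@sequence, id = sprintf("phantom-%d", spec@seed))
}

# Anti-aliased polyline: coverage = clamp(width/2 + 0.5 - distance, 0, 1),
# blended over the base image.
drawFilament <- function(img, pts, width, intensity) {
  n <- nrow(img)
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), n), n, n)
  d <- matrix(Inf, n, n)
  for (k in seq_len(nrow(pts) - 1L)) {
    p <- pts[k, ]; q <- pts[k + 1L, ]
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    l2 <- vx^2 + vy^2
    tt <- ((X - p[1]) * vx + (Y - p[2]) * vy) / l2
    tt <- pmin(pmax(tt, 0), 1)
    d <- pmin(d, sqrt((X - (p[1] + tt * vx))^2 + (Y - (p[2] + tt * vy))^2))
  }
  cov <- pmin(pmax(width / 2 + 0.5 - d, 0), 1)
  img * (1 - cov) + intensity * cov
}

addGaussianBump <- function(img, x, y, amplitude, sigma) {
  n1 <- nrow(img); n2 <- ncol(img)
  gx <- exp(-((seq_len(n2) - x)^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(n1) - y)^2) / (2 * sigma^2))
  img + amplitude * outer(gy, gx)
}

#' Embed a Gaussian fiducial target into a slice
#'
#' Adds a 2-D Gaussian bump of the given amplitude and width centred at
#' the (sub-pixel) coordinate, clipping the result to \[0, 1\].
#'
#' @param slice an \linkS4class{MRISlice}.
#' @param coord a \linkS4class{TargetCoordinate} (x = column, y = row).
#' @param amplitude peak height added at the centre.
#' @param sigma Gaussian width in pixels (> 0).
#' @return A new \linkS4class{MRISlice}.
#' @export
embedFiducial <- function(slice, coord, amplitude, sigma) {
  stopifnot(is(coord, "TargetCoordinate"))
  p <- pixels(slice)
  if (coord@x < 1 || coord@x > ncol(p) || coord@y < 1 || coord@y > nrow(p))
    stopValidation("coord: fiducial centre must lie inside image bounds")
  if (sigma <= 0) stopValidation("sigma: must be > 0")
  out <- clip01(addGaussianBump(p, coord@x, coord@y, amplitude, sigma))
  MRISlice(out, bitDepthSource = slice@bitDepthSource, spacing = slice@spacing,
           seqTag = slice@seqTag, id = slice@id)
}

#' Generate a cohort of phantom slices
#'
#' Derives one \linkS4class{PhantomSpec} per slice from the base spec: the
#' per-slice seed comes deterministically from the cohort seed, region
#' geometry is jittered within \[0.95, 1.05\] of the base scale, filament
#' control points are jittered by up to 3 px and fiducial centres (when
#' present) by up to 2 px. The manifest records every derived spec.
#'
#' @param n number of slices (>= 1).
#' @param baseSpec a \linkS4class{PhantomSpec} giving the shared conditions.
#' @param seed cohort seed.
#' @param outDir optional directory; when given, slices are written as 8-bit
#'   PNG and the manifest as manifest.csv.
#' @return list(slices = list of \linkS4class{MRISlice},
#'   specs = list of \linkS4class{PhantomSpec}, manifest = data.frame).
#' @export
generateCohort <- function(n, baseSpec, seed, outDir = NULL) {
  if (n < 1) stopValidation("n: must be >= 1")
  specs <- withSeed(seed, lapply(seq_len(n), function(i) {
    sp <- baseSpec
    sp@seed <- deriveSeed(seed, i)
    gs <- baseSpec@geometryScale * runif(1, 0.95, 1.05)
    sp@geometryScale <- min(max(gs, 0.8), 1.2)
    if (length(sp@filament)) {
      jit <- matrix(runif(length(sp@filament$points), -3, 3),
                    ncol = 2)
      sp@filament$points <- sp@filament$points + jit
    }
    if (length(sp@fiducial)) {
      sp@fiducial$x <- sp@fiducial$x + runif(1, -2, 2)
      sp@fiducial$y <- sp@fiducial$y + runif(1, -2, 2)
    }
    sp
  }))
  slices <- lapply(specs, generatePhantom)
  for (i in seq_len(n)) slices[[i]]@id <- sprintf("phantom-%03d", i)
  man <- do.call(rbind, lapply(seq_len(n), function(i) {
    sp <- specs[[i]]
    data.frame(id = slices[[i]]@id, seed = sp@seed, size = sp@size,
               sequence = sp@sequence, noise_sigma = sp@noiseSigma,
               geometry_scale = sp@geometryScale,
               filament = length(sp@filament) > 0,
               fid_x = if (length(sp@fiducial)) sp@fiducial$x else NA_real_,
               fid_y = if (length(sp@fiducial)) sp@fiducial$y else NA_real_,
               fid_amplitude = if (length(sp@fiducial)) sp@fiducial$amplitude
                               else NA_real_,
               fid_sigma = if (length(sp@fiducial)) sp@fiducial$sigma
                           else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    man$file <- paste0(man$id, ".png")
    for (i in seq_len(n))
      writeSliceImage(slices[[i]], file.path(outDir, man$file[i]), "png")
    write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
  }
  list(slices = slices, specs = specs, manifest = man)
}

#' Rician cumulative distribution function
#'
#' CDF of the magnitude of a complex signal \eqn{\nu + n_1 + i n_2} with
#' Gaussian components of scale sigma, via the equivalent noncentral
#' chi-squared law: \eqn{(X/\sigma)^2 \sim \chi^2_2((\nu/\sigma)^2)}.
#' Used to verify the phantom noise statistics.
#'
#' @param q quantiles (>= 0).
#' @param nu underlying noiseless signal level.
#' @param sigma noise scale (> 0).
#' @return P(X <= q).
#' @export
riceCDF <- function(q, nu, sigma) {
  stats::pchisq((q / sigma)^2, df = 2, ncp = (nu / sigma)^2)
}
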