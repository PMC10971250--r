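# Independent single-patch backprop + SGDM oracle for a depth-2, width-1
# network, written as direct shift-and-sum arithmetic (no shared code with
# src/). Used by the optimizer tests.

shiftImg <- function(img, di, dj) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  si <- (1:H) + di; sj <- (1:W) + dj
  okI <- si >= 1 & si <= H; okJ <- sj >= 1 & sj <= W
  out[okI, okJ] <- img[si[okI], sj[okJ]]
  out
}

handGrad2 <- function(k1, b1, k2, b2, x, r) {
  z1 <- convOracle(x, k1, b1); a1 <- pmax(z1, 0)
  pred <- convOracle(a1, k2, b2)
  d2 <- (pred - r) / length(x)
  gk <- function(input, delta) {
    g <- matrix(0, 3, 3)
    for (di in -1:1) for (dj in -1:1)
      g[di + 2, dj + 2] <- sum(delta * shiftImg(input, di, dj))
    g
  }
  d1 <- matrix(0, nrow(x), ncol(x))
  for (di in -1:1) for (dj in -1:1)
    d1 <- d1 + shiftImg(d2, -di, -dj) * k2[di + 2, dj + 2]
  d1 <- d1 * (z1 > 0)
  list(gk1 = gk(x, d1), gb1 = sum(d1), gk2 = gk(a1, d2), gb2 = sum(d2),
       loss = 0.5 * mean((pred - r)^2))
}

# One hand-computed SGDM step: decay -> global clip -> momentum -> update.
handStep <- function(k1, b1, k2, b2, v, g, lr, mom = 0.9, l2 = 1e-4,
                     thr = 0.01) {
  gw1 <- g$gk1 + l2 * k1; gw2 <- g$gk2 + l2 * k2
  gb1 <- g$gb1; gb2 <- g$gb2
  nrm <- sqrt(sum(gw1^2) + sum(gw2^2) + gb1^2 + gb2^2)
  if (nrm > thr) {
    sc <- thr / nrm
    gw1 <- gw1 * sc; gw2 <- gw2 * sc; gb1 <- gb1 * sc; gb2 <- gb2 * sc
  }
  v$k1 <- mom * v$k1 - lr * gw1; v$b1 <- mom * v$b1 - lr * gb1
  v$k2 <- mom * v$k2 - lr * gw2; v$b2 <- mom * v$b2 - lr * gb2
  list(k1 = k1 + v$k1, b1 = b1 + v$b1, k2 = k2 + v$k2, b2 = b2 + v$b2, v = v)
}

onePatchSet <- function(x, r, patch) {
  new("TrainingSet", x = array(x, c(patch, patch, 1)),
      yTrue = array(x + r, c(patch, patch, 1)),
      r = array((x + r) - x, c(patch, patch, 1)),
      scale = 2L, patchSize = as.integer(patch),
      manifest = data.frame(slice_id = "oracle", aug = 0L,
                            aug_seed = NA_integer_, scale = 2L,
                            n_patches = 1L, shuffle_seed = 1L))
}
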