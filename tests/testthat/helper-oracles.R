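# Brute-force oracles and small fixture builders, independent of the
# implementation paths they check.

# Erosion oracle: a pixel survives iff every disk offset lands on a true
# pixel inside the raster.
bruteErode <- function(m, diameter) {
  r <- (diameter - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ok <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (di * di + dj * dj > r * r) next
      si <- i + di; sj <- j + dj
      if (si < 1 || si > H || sj < 1 || sj > W || !m[si, sj]) {
        ok <- FALSE
      }
    }
    out[i, j] <- ok
  }
  out
}

# Median-filter oracle: sliding window with symmetric reflection (the edge
# pixel is included in the reflection).
bruteMedian <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  half <- k %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) i <- if (i < 1) 1 - i else 2 * n + 1 - i
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    w <- numeric(0)
    for (di in -half:half) for (dj in -half:half)
      w <- c(w, x[refl(i + di, H), refl(j + dj, W)])
    out[i, j] <- median(w)
  }
  out
}

randomImage <- function(h, w, mean = 30, sd = 20, subject = "subject0") {
  HUImage(matrix(rnorm(h * w, mean, sd), h, w), subjectId = subject)
}

randomMask <- function(h, w, p = 0.6) {
  m <- matrix(runif(h * w) < p, h, w)
  if (!any(m)) m[sample(h * w, 3)] <- TRUE
  brainMask(m)
}

zeroTiltPhysics <- function(name = "80/150Sn", sigmaLow = 0, sigmaHigh = 0) {
  z <- c(background = 0, csf = 0, white = 0, gray = 0, hemorrhage = 0)
  physicsConfig(name, tiltLow = z, tiltHigh = z, noiseSigmaLow = sigmaLow,
                noiseSigmaHigh = sigmaHigh)
}

# Lookup table built directly from a value matrix (for inpainting tests).
tableFromMatrix <- function(v, obs) {
  n1 <- nrow(v); n2 <- ncol(v)
  new("LookupTable", values = ifelse(obs, v, NA_real_), observed = obs,
      counts = obs * 1, lowEdges = 0:n1, highEdges = 0:n2,
      fillValuePolicy = "none", clampedSamples = 0)
}

# Convex-hull membership for integer cell coordinates.
pointsInHull <- function(pts, hullPts) {
  h <- hullPts[chull(hullPts), , drop = FALSE]
  nh <- nrow(h)
  apply(pts, 1, function(q) {
    s <- 0
    for (i in seq_len(nh)) {
      a <- h[i, ]; b <- h[(i %% nh) + 1, ]
      cr <- (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
      if (abs(cr) < 1e-12) next
      if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
    }
    TRUE
  })
}

# A tiny trained-free training sample around a given target.
sampleFromMatrices <- function(low, high, lvnc, tnc, mask, size = nrow(low)) {
  makeTrainingSamples(dectPair(HUImage(low), HUImage(high)),
                      HUImage(lvnc), HUImage(tnc), brainMask(mask), size)
}
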