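# Synthetic DECT brain-phantom generator: tissue scenes, TNC rendering,
# dual-energy forward simulation and patient-level dataset assembly.

.TISSUE_LEVELS <- c(background = 0L, csf = 1L, white = 2L, gray = 3L,
                    hemorrhage = 4L)

#' Default mean HU per tissue class
#' @return named numeric vector.
#' @export
defaultBaseHU <- function() {
  c(background = -1000, csf = 8, white = 25, gray = 38, hemorrhage = 65)
}

#' Scene-generation parameters
#'
#' @param lesionProb probability that each potential hemorrhage lesion is
#'   present.
#' @param maxLesions maximum number of lesions.
#' @param axisFracRange range of ellipse semi-axes as a fraction of the
#'   raster dimensions; with the default (0.30, 0.42) the brain covers
#'   roughly 28-55% of the raster.
#' @param iodineBumps number of Gaussian contrast-enhancement foci.
#' @param iodinePeakRange peak iodine concentration range (arbitrary units).
#' @param perfusion uniform baseline iodine concentration inside the brain.
#' @param baseHU named per-class mean HU.
#' @return parameter list for \code{\link{makeScene}}.
#' @export
sceneParams <- function(lesionProb = 0.5, maxLesions = 2L,
                        axisFracRange = c(0.30, 0.42), iodineBumps = 3L,
                        iodinePeakRange = c(0.2, 1.0), perfusion = 0.1,
                        baseHU = defaultBaseHU()) {
  list(lesionProb = lesionProb, maxLesions = as.integer(maxLesions),
       axisFracRange = axisFracRange, iodineBumps = as.integer(iodineBumps),
       iodinePeakRange = iodinePeakRange, perfusion = perfusion,
       baseHU = baseHU)
}

# Smooth pseudo-random field (sum of a few random cosines), sd ~ 1.
.smoothField <- function(rr, cc, H, W, nWaves = 4L) {
  f <- 0
  for (i in seq_len(nWaves)) {
    kx <- runif(1, 0.5, 2.5) / W
    ky <- runif(1, 0.5, 2.5) / H
    ph <- runif(1, 0, 2 * pi)
    f <- f + runif(1, 0.5, 1) * cos(2 * pi * (kx * cc + ky * rr) + ph)
  }
  s <- sd(as.vector(f))
  if (s > 0) f / s else f
}

#' Generate a synthetic brain scene
#'
#' Builds an elliptical "brain" subdivided into CSF (ventricles and a
#' sulcal rim), gray and white matter compartments with smooth random
#' boundaries, optional elliptical hemorrhage lesions, and a smooth
#' non-negative iodine concentration map that is zero outside the brain.
#' Deterministic given \code{seed}.
#'
#' @param height,width raster dimensions (>= 16).
#' @param seed integer seed.
#' @param params list from \code{\link{sceneParams}}.
#' @param subjectId scene identifier (defaults to "scene<seed>").
#' @return a \linkS4class{PhantomScene}.
#' @export
makeScene <- function(height, width, seed, params = sceneParams(),
                      subjectId = sprintf("scene%d", seed)) {
  if (height < 16L || width < 16L) stop("degenerate dimensions (< 16)")
  withSeed(seed, {
    H <- as.integer(height); W <- as.integer(width)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    cy <- H * (0.5 + runif(1, -0.04, 0.04))
    cx <- W * (0.5 + runif(1, -0.04, 0.04))
    ay <- H * runif(1, params$axisFracRange[1], params$axisFracRange[2])
    ax <- W * runif(1, params$axisFracRange[1], params$axisFracRange[2])
    rho <- sqrt(((rr - cy) / ay)^2 + ((cc - cx) / ax)^2)
    mask <- rho <= 1

    labels <- matrix(.TISSUE_LEVELS[["background"]], H, W)
    labels[mask] <- .TISSUE_LEVELS[["white"]]

    # gray matter: outer cortical band with an irregular inner boundary
    fGray <- .smoothField(rr, cc, H, W)
    grayStart <- 0.70 + 0.06 * fGray
    labels[mask & rho > grayStart] <- .TISSUE_LEVELS[["gray"]]

    # sulcal CSF rim at the brain edge
    fRim <- .smoothField(rr, cc, H, W)
    rimStart <- 0.93 + 0.03 * fRim
    labels[mask & rho > rimStart] <- .TISSUE_LEVELS[["csf"]]

    # ventricles: small central ellipse with wobble
    vy <- cy + H * runif(1, -0.03, 0.03)
    vx <- cx + W * runif(1, -0.03, 0.03)
    fV <- .smoothField(rr, cc, H, W)
    rhoV <- sqrt(((rr - vy) / (0.22 * ay))^2 + ((cc - vx) / (0.30 * ax))^2)
    labels[mask & (rhoV + 0.15 * fV) <= 1] <- .TISSUE_LEVELS[["csf"]]

    # hemorrhage lesions
    nLes <- sum(runif(params$maxLesions) < params$lesionProb)
    for (i in seq_len(nLes)) {
      th <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.55)
      ly <- cy + rad * ay * sin(th)
      lx <- cx + rad * ax * cos(th)
      la <- runif(1, 0.05, 0.12)
      rhoL <- sqrt(((rr - ly) / (la * H))^2 + ((cc - lx) / (la * W))^2)
      labels[mask & rhoL <= 1] <- .TISSUE_LEVELS[["hemorrhage"]]
    }

    # iodine: Gaussian enhancement foci + mild uniform perfusion
    iod <- matrix(0, H, W)
    for (i in seq_len(params$iodineBumps)) {
      th <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.7)
      by <- cy + rad * ay * sin(th)
      bx <- cx + rad * ax * cos(th)
      sg <- runif(1, 0.05, 0.15) * min(H, W)
      pk <- runif(1, params$iodinePeakRange[1], params$iodinePeakRange[2])
      iod <- iod + pk * exp(-((rr - by)^2 + (cc - bx)^2) / (2 * sg^2))
    }
    iod <- iod + params$perfusion
    iod[!mask] <- 0

    new("PhantomScene", labels = labels, baseHU = params$baseHU,
        iodineMap = iod, mask = brainMask(mask), subjectId = subjectId,
        seed = as.integer(seed))
  })
}

.classHU <- function(scene, perClass) {
  lut <- perClass[c("background", "csf", "white", "gray", "hemorrhage")]
  matrix(lut[scene@labels + 1L], nrow(scene@labels), ncol(scene@labels))
}

#' Per-class TNC spectral offsets
#'
#' The true non-contrast series is a single-energy acquisition whose
#' effective spectrum differs from both DECT energies and from any VNC
#' blend derived from them, so each tissue shows a systematic offset of up
#' to ~15 HU between TNC and VNC. These defaults emulate that
#' anatomy-dependent discrepancy; it is the signal the residual network is
#' trained to remove.
#'
#' @return named numeric vector of per-class HU offsets.
#' @export
defaultTNCOffset <- function() {
  c(background = 0, csf = -3, white = 6, gray = 9, hemorrhage = 14)
}

#' Render the ground-truth non-contrast image of a scene
#'
#' Pixel value = per-class mean HU, plus an optional per-class spectral
#' offset, plus independent Gaussian noise; no iodine contribution.
#' Deterministic given \code{seed}. With \code{offset = NULL} (the default)
#' the noiseless TNC equals the per-class base HU exactly, which is the
#' configuration in which a spectrally consistent material decomposition of
#' the noiseless zero-tilt DECT simulation reproduces it.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param noiseSigma Gaussian noise SD in HU (>= 0).
#' @param seed integer seed.
#' @param sliceId slice identifier.
#' @param offset optional named per-class HU offset vector (see
#'   \code{\link{defaultTNCOffset}}).
#' @return an \linkS4class{HUImage}.
#' @export
renderTNC <- function(scene, noiseSigma = 0, seed = scene@seed,
                      sliceId = "slice0", offset = NULL) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  base <- .classHU(scene, scene@baseHU)
  if (!is.null(offset)) base <- base + .classHU(scene, offset)
  p <- withSeed(seed, base + if (noiseSigma > 0)
    rnorm(length(base), 0, noiseSigma) else 0)
  HUImage(matrix(p, nrow(base), ncol(base)), sliceId = sliceId,
          subjectId = scene@subjectId)
}

#' Named acquisition-physics presets
#'
#' Two presets mirror the 80/150Sn and 100/150Sn tube-voltage protocols:
#' the 80 kVp series has larger spectral tissue offsets and more noise than
#' the 100 kVp series; both use the protocol iodine low/high enhancement
#' ratio of 2.12.
#'
#' @param name "80/150Sn" or "100/150Sn" (any other name gives a custom
#'   config from the remaining arguments).
#' @param iodineRatio iodine low/high enhancement ratio.
#' @param iodineHighGain HU per unit concentration at the high energy.
#' @param tiltLow,tiltHigh named per-class spectral offsets (HU).
#' @param noiseSigmaLow,noiseSigmaHigh noise SD (HU).
#' @return a \linkS4class{PhysicsConfig}.
#' @export
physicsConfig <- function(name = "80/150Sn", iodineRatio = 2.12,
                          iodineHighGain = 25,
                          tiltLow = NULL, tiltHigh = NULL,
                          noiseSigmaLow = NULL, noiseSigmaHigh = NULL) {
  tilt80L <- c(background = 0, csf = 1, white = 1.5, gray = 2,
               hemorrhage = 3)
  tilt80H <- c(background = 0, csf = -1, white = -1, gray = -1.5,
               hemorrhage = -2)
  if (name == "80/150Sn") {
    if (is.null(tiltLow)) tiltLow <- tilt80L
    if (is.null(tiltHigh)) tiltHigh <- tilt80H
    if (is.null(noiseSigmaLow)) noiseSigmaLow <- 3.5
    if (is.null(noiseSigmaHigh)) noiseSigmaHigh <- 2.0
  } else if (name == "100/150Sn") {
    if (is.null(tiltLow)) tiltLow <- 0.7 * tilt80L
    if (is.null(tiltHigh)) tiltHigh <- 0.7 * tilt80H
    if (is.null(noiseSigmaLow)) noiseSigmaLow <- 2.5
    if (is.null(noiseSigmaHigh)) noiseSigmaHigh <- 2.0
  } else {
    if (is.null(tiltLow)) tiltLow <- tilt80L
    if (is.null(tiltHigh)) tiltHigh <- tilt80H
    if (is.null(noiseSigmaLow)) noiseSigmaLow <- 3.0
    if (is.null(noiseSigmaHigh)) noiseSigmaHigh <- 2.0
  }
  new("PhysicsConfig", name = name, iodineRatio = iodineRatio,
      iodineHighGain = iodineHighGain, tiltLow = tiltLow,
      tiltHigh = tiltHigh, noiseSigmaLow = noiseSigmaLow,
      noiseSigmaHigh = noiseSigmaHigh)
}

#' Construct a DECTPair
#' @param low,high \linkS4class{HUImage} objects.
#' @param physicsName physics label.
#' @return a \linkS4class{DECTPair}.
#' @export
dectPair <- function(low, high, physicsName = "custom") {
  new("DECTPair", low = low, high = high, physicsName = physicsName)
}

#' Simulate a dual-energy acquisition of a scene
#'
#' Forward model per pixel: low = base + tiltLow(class) + r*g*iodine +
#' noise(sigmaLow); high = base + tiltHigh(class) + g*iodine +
#' noise(sigmaHigh), with r the iodine low/high enhancement ratio and g the
#' high-energy gain. In the noiseless model the iodine enhancement obeys the
#' low/high ratio r exactly at every pixel.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param physics a \linkS4class{PhysicsConfig}.
#' @param seed integer seed.
#' @param sliceId slice identifier.
#' @return a \linkS4class{DECTPair}.
#' @export
simulateDECT <- function(scene, physics, seed = scene@seed,
                         sliceId = "slice0") {
  base <- .classHU(scene, scene@baseHU)
  tl <- .classHU(scene, physics@tiltLow)
  th <- .classHU(scene, physics@tiltHigh)
  r <- physics@iodineRatio; g <- physics@iodineHighGain
  n <- length(base)
  noise <- withSeed(seed, list(
    low = if (physics@noiseSigmaLow > 0)
      rnorm(n, 0, physics@noiseSigmaLow) else 0,
    high = if (physics@noiseSigmaHigh > 0)
      rnorm(n, 0, physics@noiseSigmaHigh) else 0))
  lowP <- base + tl + r * g * scene@iodineMap + noise$low
  highP <- base + th + g * scene@iodineMap + noise$high
  dectPair(HUImage(matrix(lowP, nrow(base), ncol(base)), sliceId,
                   scene@subjectId),
           HUImage(matrix(highP, nrow(base), ncol(base)), sliceId,
                   scene@subjectId),
           physicsName = physics@name)
}

# Largest-remainder apportionment with a >= 1 guarantee per partition.
.apportion <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- raw - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(rem, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  while (any(sizes == 0)) {
    i <- which(sizes == 0)[1]
    j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1
    sizes[j] <- sizes[j] - 1
  }
  as.integer(sizes)
}

#' Generate a synthetic DECT dataset with patient-level partitioning
#'
#' Each scene plays the role of one synthetic patient and is assigned to
#' exactly one of the train/validation/test partitions (largest-remainder
#' apportionment of scene counts; every partition receives at least one
#' scene). All slices of a scene share its partition. Deterministic given
#' \code{seed}.
#'
#' @param nScenes number of scenes (>= 3).
#' @param splitFractions train/validation/test fractions (positive, sum 1).
#' @param physics a \linkS4class{PhysicsConfig}.
#' @param seed integer seed.
#' @param height,width scene dimensions.
#' @param slicesPerScene noise realizations per scene.
#' @param tncNoiseSigma TNC noise SD (HU).
#' @param tncOffset per-class TNC spectral offset
#'   (\code{\link{defaultTNCOffset}}; NULL for none).
#' @param params scene parameters (\code{\link{sceneParams}}).
#' @param outDir if non-NULL, per-slice array archives are written here and
#'   their paths recorded in the manifest.
#' @return list with \code{manifest} (data.frame: subject_id, slice_id,
#'   partition and, when written, file paths) and \code{slices} (per-slice
#'   lists with elements pair, tnc, mask, scene index).
#' @export
makeDataset <- function(nScenes, splitFractions = c(0.745, 0.145, 0.110),
                        physics = physicsConfig(), seed = 1L,
                        height = 64L, width = 64L, slicesPerScene = 1L,
                        tncNoiseSigma = 2, tncOffset = defaultTNCOffset(),
                        params = sceneParams(), outDir = NULL) {
  if (nScenes < 3L) stop("need at least 3 scenes to populate all partitions")
  if (length(splitFractions) != 3L || any(splitFractions <= 0))
    stop("splitFractions must be 3 positive numbers")
  if (abs(sum(splitFractions) - 1) > 1e-9)
    stop("splitFractions must sum to 1")
  seeds <- deriveSeeds(seed, nScenes * (1L + 2L * slicesPerScene) + 1L)
  permSeed <- seeds[length(seeds)]
  sizes <- .apportion(nScenes, splitFractions)
  perm <- withSeed(permSeed, sample.int(nScenes))
  part <- character(nScenes)
  part[perm[seq_len(sizes[1])]] <- "train"
  part[perm[sizes[1] + seq_len(sizes[2])]] <- "validation"
  part[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"

  slices <- list()
  rows <- list()
  si <- 0L
  for (k in seq_len(nScenes)) {
    base <- (k - 1L) * (1L + 2L * slicesPerScene)
    scene <- makeScene(height, width, seeds[base + 1L], params,
                       subjectId = sprintf("scene%03d", k))
    for (s in seq_len(slicesPerScene)) {
      sid <- sprintf("slice%d", s)
      tnc <- renderTNC(scene, tncNoiseSigma, seeds[base + 2L * s], sid,
                       offset = tncOffset)
      pair <- simulateDECT(scene, physics, seeds[base + 2L * s + 1L], sid)
      si <- si + 1L
      entry <- list(pair = pair, tnc = tnc, mask = scene@mask, scene = k)
      row <- data.frame(subject_id = scene@subjectId, slice_id = sid,
                        partition = part[k], stringsAsFactors = FALSE)
      if (!is.null(outDir)) {
        stem <- file.path(outDir, sprintf("sub-%03d_slice-%d", k, s))
        writeHUImage(pair@low, paste0(stem, "_low.rds"))
        writeHUImage(pair@high, paste0(stem, "_high.rds"))
        writeHUImage(tnc, paste0(stem, "_tnc.rds"), mask = scene@mask)
        row$path_low <- paste0(stem, "_low.rds")
        row$path_high <- paste0(stem, "_high.rds")
        row$path_tnc <- paste0(stem, "_tnc.rds")
      }
      slices[[si]] <- entry
      rows[[si]] <- row
    }
  }
  list(manifest = do.call(rbind, rows), slices = slices,
       physics = physics, seed = as.integer(seed))
}
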