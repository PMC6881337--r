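tinyConfig <- function(channels = 4L, size = 8L, dropout = 0,
                       norm = "batch") {
  networkConfig("desk", channels = channels, inputSize = size,
                dropoutRate = dropout, normalization = norm)
}

test_that("training samples carry normalized channels and HU targets", {
  set.seed(51)
  low <- matrix(rnorm(64, 40, 10), 8); high <- matrix(rnorm(64, 35, 10), 8)
  lvnc <- matrix(rnorm(64, 30, 5), 8); tnc <- matrix(rnorm(64, 32, 5), 8)
  m <- matrix(TRUE, 8, 8)
  # lvnc == tnc -> target identically zero
  s0 <- sampleFromMatrices(low, high, tnc, tnc, m)
  expect_true(all(s0@target == 0))
  # native size: channels are the normalized originals
  s <- sampleFromMatrices(low, high, lvnc, tnc, m)
  expect_equal(s@input[, , 1], (low + 100) / 400)
  expect_equal(s@input[, , 3], (lvnc + 100) / 400)
  expect_equal(s@target, tnc - lvnc)
  # constant difference survives area-average downsampling
  s7 <- sampleFromMatrices(low, high, lvnc, lvnc + 7, m, size = 4)
  expect_equal(s7@target, matrix(7, 4, 4))
  # target + L-VNC reproduces TNC exactly at native resolution
  expect_equal(s@target + lvnc, tnc)
  expect_error(sampleFromMatrices(low, high, lvnc, matrix(0, 4, 4), m),
               "mismatch")
  # mask coverage threshold at 0.5
  mHalf <- matrix(FALSE, 8, 8); mHalf[1:2, 1:2] <- TRUE  # one full block
  sH <- sampleFromMatrices(low, high, lvnc, tnc, mHalf, size = 4)
  expect_identical(sH@mask@pixels[1, 1], TRUE)
  expect_false(any(sH@mask@pixels[-1, ]))
})

test_that("the network honors its shape, parameter and zero contracts", {
  cfg <- networkConfig("desk")  # 8 channels, 64 x 64
  net <- buildNetwork(cfg, 1L)
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y <- dectdnc:::.netForward(net@params, net@state, cfg, x)$y
  expect_equal(dim(y), c(64L, 64L, 1L, 2L))
  # closed-form parameter count for channels = 8, kernel = 3, 3 x 3 blocks
  C <- 8; k <- 3; nBlocks <- 9
  convIn <- 3 * k * k * C + C
  perBlock <- 2 * (C * k * k * C + C) + 4 * C  # two convs + two BN layers
  convOut <- C + 1
  expect_equal(sum(lengths(netParams(net))),
               convIn + nBlocks * perBlock + convOut)
  # zeroed final layer gives the zero map
  p <- netParams(net)
  p[["conv_out.wt"]][] <- 0; p[["conv_out.b"]][] <- 0
  netParams(net) <- p
  y0 <- dectdnc:::.netForward(net@params, net@state, cfg, x)$y
  expect_true(all(y0 == 0))
  # initialization is deterministic given the seed
  expect_identical(netParams(buildNetwork(cfg, 5L)),
                   netParams(buildNetwork(cfg, 5L)))
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(61)
  cfg <- tinyConfig()
  net <- buildNetwork(cfg, 7L)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  tg <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  m <- array(rbinom(128, 1, 0.7), c(8, 8, 1, 2))
  lossAt <- function(params) {
    fwd <- dectdnc:::.netForward(params, net@state, cfg, x, training = TRUE,
                                 keepCache = TRUE)
    dectdnc:::.maskedRMSELoss(fwd$y, tg, m)$loss
  }
  fwd <- dectdnc:::.netForward(net@params, net@state, cfg, x,
                               training = TRUE, keepCache = TRUE)
  lo <- dectdnc:::.maskedRMSELoss(fwd$y, tg, m)
  gr <- dectdnc:::.netBackward(net@params, cfg, fwd, lo$dpred)
  eps <- 1e-5
  for (nm in c("conv_in.wt", "blk1.conv1.wt", "blk5.conv2.wt",
               "blk9.bn2.gamma", "blk3.bn1.beta", "conv_out.wt",
               "conv_out.b")) {
    for (ii in seq_len(min(2, length(net@params[[nm]])))) {
      pp <- net@params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- net@params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][ii]),
                1e-6 * max(1, abs(num)))
    }
  }
})

test_that("the masked loss ignores pixels outside the brain mask", {
  set.seed(62)
  cfg <- tinyConfig()
  net <- buildNetwork(cfg, 3L)
  x <- array(rnorm(8 * 8 * 3 * 1), c(8, 8, 3, 1))
  tg <- array(rnorm(64), c(8, 8, 1, 1))
  m <- array(0, c(8, 8, 1, 1)); m[3:6, 3:6, 1, 1] <- 1
  y <- dectdnc:::.netForward(net@params, net@state, cfg, x)$y
  l1 <- dectdnc:::.maskedRMSELoss(y, tg, m)$loss
  tg2 <- tg; tg2[m == 0] <- 1e6  # corrupt only unmasked pixels
  l2 <- dectdnc:::.maskedRMSELoss(y, tg2, m)$loss
  expect_identical(l1, l2)
})

test_that("zeroing the residual branches reduces to the projection path", {
  set.seed(63)
  cfg <- tinyConfig(norm = "none")
  net <- buildNetwork(cfg, 11L)
  p <- netParams(net)
  for (nm in names(p))
    if (grepl("^blk", nm)) p[[nm]][] <- 0
  netParams(net) <- p
  x <- array(rnorm(8 * 8 * 3 * 1), c(8, 8, 3, 1))
  full <- dectdnc:::.netForward(net@params, net@state, cfg, x)$y
  a <- dectdnc:::.nn_conv_fwd(x, p[["conv_in.wt"]], p[["conv_in.b"]], 3L, 1L)
  direct <- dectdnc:::.nn_conv_fwd(a, p[["conv_out.wt"]], p[["conv_out.b"]],
                                   1L, 1L)
  expect_equal(full, direct, tolerance = 1e-12)
})

test_that("training reaches the zero-loss minimum and stops on the plateau", {
  set.seed(64)
  cfg <- tinyConfig()
  net <- buildNetwork(cfg, 2L)
  p <- netParams(net)
  p[["conv_out.wt"]][] <- 0; p[["conv_out.b"]][] <- 0
  netParams(net) <- p
  mkSample <- function() {
    low <- matrix(rnorm(64, 40, 5), 8); high <- matrix(rnorm(64, 35, 5), 8)
    lvnc <- matrix(rnorm(64, 30, 5), 8)
    sampleFromMatrices(low, high, lvnc, lvnc, matrix(TRUE, 8, 8))
  }
  tr <- replicate(3, mkSample(), simplify = FALSE)
  va <- replicate(2, mkSample(), simplify = FALSE)
  res <- trainModel(net, tr, va, patience = 2L, maxEpochs = 10L, seed = 5L)
  expect_equal(res$history@valLoss[1], 0)
  expect_equal(min(res$history@valLoss), 0)
  expect_equal(res$history@stopReason, "plateau")
  expect_lt(res$history@epochsRun, 10L)
})

test_that("a small network overfits noiseless samples", {
  set.seed(65)
  cfg <- networkConfig("desk", channels = 8L, inputSize = 16L,
                       dropoutRate = 0, learningRate = 3e-3)
  net <- buildNetwork(cfg, 4L)
  mkSample <- function(s) {
    set.seed(s)
    low <- matrix(rnorm(256, 40, 15), 16)
    high <- matrix(rnorm(256, 35, 15), 16)
    lvnc <- 0.5 * low + 0.5 * high
    tnc <- lvnc + 10 + 0.1 * low  # smooth deterministic bias
    sampleFromMatrices(low, high, lvnc, tnc, matrix(TRUE, 16, 16))
  }
  tr <- lapply(1:4, mkSample)
  res <- trainModel(net, tr, tr, patience = 100L, maxEpochs = 60L,
                    seed = 9L, tol = 0)
  h <- res$history
  expect_lt(h@trainLoss[h@epochsRun], 0.10 * h@trainLoss[1])
  # the trained model reproduces its training targets
  pred <- predictDifference(res$model, tr[[1]])
  rmse <- sqrt(mean((pixels(pred) - tr[[1]]@target)^2))
  expect_lt(rmse, 2)
  # inference is deterministic (dropout disabled)
  expect_identical(pixels(predictDifference(res$model, tr[[1]])),
                   pixels(pred))
})

test_that("training runs are reproducible seed for seed", {
  set.seed(66)
  cfg <- tinyConfig(dropout = 0.3)
  mkSample <- function(s) {
    set.seed(s)
    low <- matrix(rnorm(64, 40, 10), 8); high <- matrix(rnorm(64, 35, 10), 8)
    lvnc <- 0.5 * low + 0.5 * high
    sampleFromMatrices(low, high, lvnc, lvnc + 5, matrix(TRUE, 8, 8))
  }
  tr <- lapply(1:5, mkSample); va <- lapply(6:7, mkSample)
  r1 <- trainModel(buildNetwork(cfg, 3L), tr, va, patience = 3L,
                   maxEpochs = 4L, seed = 21L)
  r2 <- trainModel(buildNetwork(cfg, 3L), tr, va, patience = 3L,
                   maxEpochs = 4L, seed = 21L)
  expect_equal(r1$history@valLoss, r2$history@valLoss, tolerance = 1e-6)
  expect_equal(r1$history@trainLoss, r2$history@trainLoss,
               tolerance = 1e-6)
  expect_equal(netParams(r1$model), netParams(r2$model), tolerance = 1e-6)
})

test_that("learning improves on the physics baseline across seeds", {
  # Small-scale version of the headline property: TNC = L-VNC + anatomy-
  # dependent bias + noise; the trained network should beat the raw L-VNC
  # on held-out scenes for >= 9 of 10 seeds.
  wins <- 0L
  for (s in 1:10) {
    ds <- makeDataset(30, c(0.6, 0.2, 0.2), physicsConfig("80/150Sn"),
                      seed = 1000 + s, height = 32, width = 32)
    basis <- materialBasis()
    slices <- lapply(ds$slices, function(sl) {
      sl$svnc <- decomposeDECT(sl$pair, basis)$vnc
      sl$emask <- erodeMask(sl$mask, 5)
      sl
    })
    part <- ds$manifest$partition
    tri <- which(part == "train"); vai <- which(part == "validation")
    tei <- which(part == "test")
    lut <- inpaintLookup(buildLookup(
      lapply(slices[tri], `[[`, "pair"),
      lapply(slices[tri], `[[`, "svnc"),
      lapply(slices[tri], `[[`, "emask"),
      lowRange = c(-100, 200), highRange = c(-100, 200)))
    slices <- lapply(slices, function(sl) {
      sl$lvnc <- medianFilterImage(applyLookup(lut, sl$pair), 5)
      sl
    })
    samples <- lapply(slices, function(sl)
      makeTrainingSamples(sl$pair, sl$lvnc, sl$tnc, sl$emask, 32))
    cfg <- networkConfig("desk", inputSize = 32L)
    res <- trainModel(buildNetwork(cfg, 2000 + s), samples[tri],
                      samples[vai], patience = 3L, maxEpochs = 6L,
                      seed = 3000 + s)
    errD <- errL <- numeric(0)
    for (i in tei) {
      sm <- samples[[i]]
      dnc <- composeDNC(
        HUImage(dectdnc:::.downsample(slices[[i]]$lvnc@pixels, 32)),
        predictDifference(res$model, sm))
      tncD <- HUImage(dectdnc:::.downsample(slices[[i]]$tnc@pixels, 32))
      lvncD <- HUImage(dectdnc:::.downsample(slices[[i]]$lvnc@pixels, 32))
      errD <- c(errD, maskedRMSE(dnc, tncD, sm@mask))
      errL <- c(errL, maskedRMSE(lvncD, tncD, sm@mask))
    }
    if (mean(errD) < mean(errL)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
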