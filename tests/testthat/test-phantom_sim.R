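test_that("scene generation is deterministic and respects its knobs", {
  s1 <- makeScene(64, 64, 42)
  s2 <- makeScene(64, 64, 42)
  expect_identical(sceneLabels(s1), sceneLabels(s2))
  expect_identical(iodineMap(s1), iodineMap(s2))
  noLesion <- makeScene(64, 64, 7, sceneParams(lesionProb = 0))
  expect_false(any(sceneLabels(noLesion) == 4L))
  expect_error(makeScene(8, 64, 1), "degenerate")
  # brain-mask coverage stays inside the geometric bounds of the ellipse
  fr <- vapply(1:100, function(s) mean(pixels(sceneMask(makeScene(64, 64, s)))),
               numeric(1))
  expect_true(all(fr > 0.2 & fr < 0.8))
})

test_that("TNC rendering follows the per-class base HU model", {
  sc <- makeScene(64, 64, 3)
  tnc0 <- renderTNC(sc, 0, 5)
  base <- c(background = -1000, csf = 8, white = 25, gray = 38,
            hemorrhage = 65)
  expect_equal(pixels(tnc0),
               matrix(base[sceneLabels(sc) + 1L], 64, 64),
               ignore_attr = TRUE)
  # CLT bound on the gray-matter mean at sigma = 2
  big <- makeScene(128, 128, 9)
  tnc <- renderTNC(big, 2, 11)
  gm <- pixels(tnc)[sceneLabels(big) == 3L]
  skip_if(length(gm) < 2000)
  expect_lt(abs(mean(gm) - 38), 0.1 * sqrt(1e4 / length(gm)) + 0.1)
  expect_identical(pixels(renderTNC(big, 2, 11)), pixels(tnc))
  expect_error(renderTNC(sc, -1), "noiseSigma")
  # spectral offset shifts each class by its configured amount
  off <- defaultTNCOffset()
  tncOff <- renderTNC(sc, 0, 5, offset = off)
  expect_equal(pixels(tncOff) - pixels(tnc0),
               matrix(off[sceneLabels(sc) + 1L], 64, 64),
               ignore_attr = TRUE)
})

test_that("the DECT forward model obeys the iodine ratio exactly", {
  sc <- makeScene(64, 64, 21)
  ph <- zeroTiltPhysics()
  pair <- simulateDECT(sc, ph, 1)
  tnc <- renderTNC(sc, 0, 1)
  # without iodine, noise or tilt: low = high = noiseless TNC
  noIod <- makeScene(64, 64, 21, sceneParams(iodineBumps = 0L,
                                             perfusion = 0))
  p0 <- simulateDECT(noIod, ph, 2)
  t0 <- renderTNC(noIod, 0, 2)
  expect_equal(pixels(lowImage(p0)), pixels(t0))
  expect_equal(pixels(highImage(p0)), pixels(t0))
  # enhancement ratio 2.12 at every enhanced pixel
  enh <- iodineMap(sc) > 0
  dl <- pixels(lowImage(pair)) - pixels(renderTNC(sc, 0, 1))
  dh <- pixels(highImage(pair)) - pixels(renderTNC(sc, 0, 1))
  expect_true(all(abs(dl[enh] / dh[enh] - 2.12) < 1e-9))
  # one unit of concentration with g = 25: +53.0 HU low, +25.0 HU high
  one <- matrix(0, 64, 64); one[30, 30] <- 1
  sc1 <- new("PhantomScene", labels = sceneLabels(sc),
             baseHU = sc@baseHU, iodineMap = one * pixels(sceneMask(sc)),
             mask = sceneMask(sc), subjectId = "s", seed = 1L)
  stopifnot(pixels(sceneMask(sc))[30, 30])
  p1 <- simulateDECT(sc1, ph, 3)
  t1 <- renderTNC(sc1, 0, 3)
  expect_equal(pixels(lowImage(p1))[30, 30] - pixels(t1)[30, 30], 53.0)
  expect_equal(pixels(highImage(p1))[30, 30] - pixels(t1)[30, 30], 25.0)
})

test_that("dataset assembly partitions patients exclusively", {
  ph <- physicsConfig("80/150Sn")
  ds <- makeDataset(10, c(0.745, 0.145, 0.110), ph, seed = 4L,
                    height = 32, width = 32)
  tab <- table(ds$manifest$partition)
  expect_true(tab[["train"]] %in% c(7L, 8L))
  expect_true(tab[["validation"]] %in% c(1L, 2L))
  expect_equal(tab[["test"]], 1L)
  # exclusivity across several seeds, with multiple slices per scene
  for (s in 1:4) {
    ds2 <- makeDataset(6, c(0.5, 0.25, 0.25), ph, seed = s, height = 32,
                       width = 32, slicesPerScene = 2)
    bySub <- split(ds2$manifest$partition, ds2$manifest$subject_id)
    expect_true(all(vapply(bySub, function(x) length(unique(x)) == 1L,
                           logical(1))))
    parts <- split(ds2$manifest$subject_id, ds2$manifest$partition)
    expect_equal(length(Reduce(intersect, parts)), 0L)
  }
  expect_error(makeDataset(10, c(1, 0, 0), ph), "positive")
  expect_error(makeDataset(10, c(0.5, 0.3, 0.3), ph), "sum to 1")
  expect_error(makeDataset(2, c(0.5, 0.25, 0.25), ph), "at least 3")
  # determinism
  dsA <- makeDataset(5, c(0.6, 0.2, 0.2), ph, seed = 99, height = 32,
                     width = 32)
  dsB <- makeDataset(5, c(0.6, 0.2, 0.2), ph, seed = 99, height = 32,
                     width = 32)
  expect_identical(dsA$manifest, dsB$manifest)
  expect_identical(pixels(dsA$slices[[3]]$tnc), pixels(dsB$slices[[3]]$tnc))
})
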