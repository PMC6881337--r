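onePixelPair <- function(low, high) {
  dectPair(HUImage(matrix(low, 1, 1)), HUImage(matrix(high, 1, 1)))
}

test_that("decomposition solves the two-base + iodine system analytically", {
  b <- materialBasis()
  # water point -> vnc 0, iodine 0
  d <- decomposeDECT(onePixelPair(0, 0), b)
  expect_equal(pixels(d$vnc)[1, 1], 0)
  expect_equal(pixels(d$iodine)[1, 1], 0)
  # hemorrhage point (68, 62), mu 0.5 -> vnc 65, iodine 0
  d <- decomposeDECT(onePixelPair(68, 62), b)
  expect_equal(pixels(d$vnc)[1, 1], 65)
  expect_equal(pixels(d$iodine)[1, 1], 0, tolerance = 1e-12)
  # water + 3 * (2.12, 1) -> vnc 0, iodine 3
  d <- decomposeDECT(onePixelPair(3 * 2.12, 3), b)
  expect_equal(pixels(d$vnc)[1, 1], 0, tolerance = 1e-12)
  expect_equal(pixels(d$iodine)[1, 1], 3)
  # singular basis rejected
  expect_error(materialBasis(hemorrhagePoint = c(2.12, 1) * 50),
               "degenerate|parallel")
})

test_that("VNC output is invariant to iodine enhancement", {
  set.seed(33)
  b <- materialBasis()
  pair <- dectPair(randomImage(40, 40, 30, 30), randomImage(40, 40, 30, 25))
  conc <- matrix(runif(1600, 0, 4), 40, 40)
  enh <- enhanceWithIodine(pair, conc, b, gain = 25)
  expect_equal(pixels(lowImage(enh)) - pixels(lowImage(pair)),
               25 * 2.12 * conc)
  expect_equal(pixels(highImage(enh)) - pixels(highImage(pair)), 25 * conc)
  v0 <- decomposeDECT(pair, b)$vnc
  v1 <- decomposeDECT(enh, b)$vnc
  expect_lt(max(abs(pixels(v1) - pixels(v0))), 1e-9)
  # concentration 0 leaves the pair unchanged
  same <- enhanceWithIodine(pair, matrix(0, 40, 40), b)
  expect_identical(pixels(lowImage(same)), pixels(lowImage(pair)))
  expect_error(enhanceWithIodine(pair, matrix(-1, 40, 40), b),
               "non-negative")
})

test_that("decomposition is linear in the input pair", {
  set.seed(44)
  b <- materialBasis()
  p1 <- dectPair(randomImage(16, 16), randomImage(16, 16))
  p2 <- dectPair(randomImage(16, 16), randomImage(16, 16))
  for (a in c(0.25, 0.5, 0.9)) {
    mix <- dectPair(
      HUImage(a * pixels(lowImage(p1)) + (1 - a) * pixels(lowImage(p2))),
      HUImage(a * pixels(highImage(p1)) + (1 - a) * pixels(highImage(p2))))
    vm <- decomposeDECT(mix, b)$vnc
    v1 <- decomposeDECT(p1, b)$vnc
    v2 <- decomposeDECT(p2, b)$vnc
    expect_equal(pixels(vm), a * pixels(v1) + (1 - a) * pixels(v2),
                 tolerance = 1e-12)
  }
})

test_that("a spectrally consistent basis closes the simulate/decompose loop", {
  sc <- makeScene(64, 64, 17)
  pair <- simulateDECT(sc, zeroTiltPhysics(), 9)
  tnc <- renderTNC(sc, 0, 9)
  vnc <- decomposeDECT(pair, neutralBasis())$vnc
  expect_lt(max(abs(pixels(vnc) - pixels(tnc))), 1e-6)
})
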