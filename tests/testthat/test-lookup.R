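test_that("the DCT transform pair inverts and matches the direct formula", {
  set.seed(2)
  x <- matrix(rnorm(40), 8, 5)
  n <- nrow(x)
  direct <- sapply(seq_len(ncol(x)), function(j)
    sapply(0:(n - 1), function(k)
      sum(x[, j] * cos(pi * (2 * (0:(n - 1)) + 1) * k / (2 * n)))))
  expect_equal(dectdnc:::.dct1(x), direct, tolerance = 1e-12)
  expect_equal(dectdnc:::.idct1(dectdnc:::.dct1(x)), x, tolerance = 1e-12)
  X <- matrix(rnorm(30 * 20), 30)
  expect_equal(dectdnc:::.idct2(dectdnc:::.dct2(X)), X, tolerance = 1e-12)
})

test_that("lookup construction bins masked pixels and averages per cell", {
  # single pixel: exactly one observed cell holding its VNC value
  pr <- dectPair(HUImage(matrix(10.2, 1, 1)), HUImage(matrix(20.7, 1, 1)))
  tb <- buildLookup(list(pr), list(HUImage(matrix(15, 1, 1))),
                    list(brainMask(matrix(TRUE, 1, 1))))
  expect_equal(sum(lookupObserved(tb)), 1L)
  i <- which(lookupObserved(tb), arr.ind = TRUE)
  # the cell covering [10, 11) x [20, 21) in HU
  expect_equal(tb@lowEdges[i[1]], 10)
  expect_equal(tb@highEdges[i[2]], 20)
  expect_equal(lookupValues(tb)[i], 15)
  # two samples in one cell average
  pr2 <- dectPair(HUImage(matrix(c(10.2, 10.4), 1)),
                  HUImage(matrix(c(20.7, 20.1), 1)))
  tb2 <- buildLookup(list(pr2), list(HUImage(matrix(c(10, 20), 1))),
                     list(brainMask(matrix(TRUE, 1, 2))))
  expect_equal(sum(lookupObserved(tb2)), 1L)
  expect_equal(lookupValues(tb2)[which(lookupObserved(tb2))], 15)
  expect_error(buildLookup(list(), list(), list()), "empty")
  # monotone coverage: adding samples never unsets an observed cell
  set.seed(91)
  mk <- function(n) {
    low <- matrix(runif(n, -50, 150), 1); high <- matrix(runif(n, -50, 150), 1)
    list(pair = dectPair(HUImage(low), HUImage(high)),
         vnc = HUImage(0.5 * low + 0.5 * high),
         mask = brainMask(matrix(TRUE, 1, n)))
  }
  a <- mk(50); b <- mk(80)
  t1 <- buildLookup(list(a$pair), list(a$vnc), list(a$mask))
  t2 <- buildLookup(list(a$pair, b$pair), list(a$vnc, b$vnc),
                    list(a$mask, b$mask))
  expect_true(all(lookupObserved(t2)[lookupObserved(t1)]))
})

test_that("observed cells track a linear VNC surface to the bin quantum", {
  set.seed(3)
  low <- matrix(runif(4000, -50, 150), 50)
  high <- matrix(runif(4000, -50, 150), 50)
  vnc <- 0.5 * low + 0.5 * high
  tb <- buildLookup(list(dectPair(HUImage(low), HUImage(high))),
                    list(HUImage(vnc)),
                    list(brainMask(matrix(TRUE, 50, 80))))
  obs <- which(lookupObserved(tb), arr.ind = TRUE)
  centerLow <- tb@lowEdges[obs[, 1]] + 0.5
  centerHigh <- tb@highEdges[obs[, 2]] + 0.5
  expected <- 0.5 * centerLow + 0.5 * centerHigh
  expect_true(all(abs(lookupValues(tb)[obs] - expected) <= 0.5))
})

test_that("inpainting preserves observed cells and fills the rest", {
  set.seed(5)
  # fully observed: identity
  v <- matrix(rnorm(100), 10)
  tb <- tableFromMatrix(v, matrix(TRUE, 10, 10))
  expect_identical(lookupValues(inpaintLookup(tb)), lookupValues(tb))
  # fully empty: zero fill
  te <- tableFromMatrix(matrix(0, 12, 12), matrix(FALSE, 12, 12))
  out <- inpaintLookup(te)
  expect_true(all(lookupValues(out) == 0))
  expect_equal(out@fillValuePolicy, "zero")
  # partial: observed values untouched, all cells finite
  obs <- matrix(runif(100) < 0.4, 10, 10)
  if (!any(obs)) obs[1, 1] <- TRUE
  tp <- tableFromMatrix(v, obs)
  ip <- inpaintLookup(tp)
  expect_identical(lookupValues(ip)[obs], v[obs])
  expect_true(all(is.finite(lookupValues(ip))))
})

test_that("a half-deleted linear plane is recovered inside the hull", {
  n <- 60
  v <- outer(2 * seq_len(n), 3 * seq_len(n), "+")
  set.seed(11)
  obs <- matrix(runif(n * n) < 0.5, n, n)
  ip <- inpaintLookup(tableFromMatrix(v, obs), nIter = 100)
  pts <- which(matrix(TRUE, n, n), arr.ind = TRUE)
  inside <- pointsInHull(pts, which(obs, arr.ind = TRUE))
  err <- abs(lookupValues(ip) - v)
  expect_lte(max(err[pts[inside, , drop = FALSE]]), 1.0)
})

test_that("application maps pixels through their cells with edge clamping", {
  # constant table -> constant image
  tb <- tableFromMatrix(matrix(7, 10, 10), matrix(TRUE, 10, 10))
  pr <- dectPair(HUImage(matrix(runif(36, 0, 10), 6)),
                 HUImage(matrix(runif(36, 0, 10), 6)))
  expect_true(all(pixels(applyLookup(tb, pr)) == 7))
  # out-of-range input clamps to the edge bin
  ramp <- tableFromMatrix(outer(1:10, rep(1, 10)), matrix(TRUE, 10, 10))
  prBig <- dectPair(HUImage(matrix(1e6, 1, 1)), HUImage(matrix(5, 1, 1)))
  expect_equal(pixels(applyLookup(ramp, prBig))[1, 1], 10)
  # unimputed table rejected
  raw <- tableFromMatrix(matrix(1, 5, 5), matrix(c(TRUE, rep(FALSE, 24)), 5))
  expect_error(applyLookup(raw, pr), "inpaintLookup")
  # in-sample fidelity on a built + imputed single-image table
  set.seed(13)
  low <- matrix(runif(900, -30, 120), 30)
  high <- matrix(runif(900, -30, 120), 30)
  vnc <- 0.4 * low + 0.6 * high
  pair <- dectPair(HUImage(low), HUImage(high))
  m <- brainMask(matrix(TRUE, 30, 30))
  lut <- inpaintLookup(buildLookup(list(pair), list(HUImage(vnc)), list(m)))
  lv <- applyLookup(lut, pair)
  expect_true(all(abs(pixels(lv) - vnc)[pixels(m)] <= 1.0))
})

test_that("median filtering matches the brute-force window oracle", {
  const <- HUImage(matrix(5, 9, 9))
  expect_identical(pixels(medianFilterImage(const, 5)), pixels(const))
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1000
  expect_equal(pixels(medianFilterImage(HUImage(imp), 5))[5, 5], 0)
  expect_error(medianFilterImage(const, 4), "odd")
  set.seed(19)
  for (k in c(3, 5)) {
    x <- matrix(rnorm(16 * 16), 16)
    expect_identical(pixels(medianFilterImage(HUImage(x), k)),
                     bruteMedian(x, k))
  }
})
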