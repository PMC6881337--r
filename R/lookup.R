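# The physics-informed core: the 2-D (low, high) -> VNC lookup table, its
# DCT-based penalized-least-squares inpainting, application to DECT pairs,
# and median filtering of the resulting L-VNC images.

# ---- DCT-II / DCT-III via FFT (even symmetric extension of length 2n) ----

# Column-wise DCT-II (unnormalized): X_k = sum_j x_j cos(pi*(2j+1)*k/(2n)).
.dct1 <- function(X) {
  n <- nrow(X)
  Y <- mvfft(rbind(X, X[n:1, , drop = FALSE]))
  w <- exp(complex(imaginary = -pi * (0:(n - 1)) / (2 * n)))
  Re(Y[seq_len(n), , drop = FALSE] * w) / 2
}

# Column-wise inverse of .dct1 (DCT-III with matching scale).
.idct1 <- function(X) {
  n <- nrow(X)
  m <- ncol(X)
  w <- exp(complex(imaginary = pi * (0:(n - 1)) / (2 * n)))
  Yh <- 2 * X * w
  Y <- matrix(complex(real = 0), 2 * n, m)
  Y[seq_len(n), ] <- Yh
  if (n > 1)
    Y[(n + 2):(2 * n), ] <- Conj(Yh[n:2, , drop = FALSE])
  Re(mvfft(Y, inverse = TRUE))[seq_len(n), , drop = FALSE] / (2 * n)
}

.dct2 <- function(X) t(.dct1(t(.dct1(X))))
.idct2 <- function(X) t(.idct1(t(.idct1(X))))

# ---- lookup construction ----

.binIndex <- function(v, edges) {
  n <- length(edges) - 1L
  i <- floor((v - edges[1]) / (edges[2] - edges[1])) + 1
  pmin(pmax(as.integer(i), 1L), n)
}

#' Build the (low, high) -> VNC lookup table
#'
#' Every masked pixel of every pair contributes its reference VNC value to
#' the cell containing its (low, high) HU pair; a cell's value is the mean
#' of its contributions. Out-of-range pairs are clamped to the edge bins and
#' counted. Cells that received no sample are flagged unobserved (NA value)
#' until \code{\link{inpaintLookup}} imputes them.
#'
#' @param pairs list of \linkS4class{DECTPair}.
#' @param vncs list of reference VNC \linkS4class{HUImage}s (aligned).
#' @param masks list of \linkS4class{BrainMask}s (aligned).
#' @param lowRange,highRange axis ranges in HU (default c(-200, 400)).
#' @param binWidth square bin width in HU (default 1).
#' @return a \linkS4class{LookupTable}.
#' @export
buildLookup <- function(pairs, vncs, masks, lowRange = c(-200, 400),
                        highRange = c(-200, 400), binWidth = 1) {
  if (length(pairs) == 0L) stop("empty input")
  if (length(vncs) != length(pairs) || length(masks) != length(pairs))
    stop("pairs, vncs and masks must be aligned lists")
  lowEdges <- seq(lowRange[1], lowRange[2], by = binWidth)
  highEdges <- seq(highRange[1], highRange[2], by = binWidth)
  nl <- length(lowEdges) - 1L
  nh <- length(highEdges) - 1L
  sums <- matrix(0, nl, nh)
  counts <- matrix(0, nl, nh)
  clamped <- 0
  total <- 0L
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    if (!identical(dim(p@low@pixels), dim(vncs[[k]]@pixels)) ||
        !identical(dim(p@low@pixels), dim(masks[[k]]@pixels)))
      stop("misaligned shapes at element ", k)
    m <- masks[[k]]@pixels
    if (!any(m)) next
    total <- total + sum(m)
    lo <- p@low@pixels[m]
    hi <- p@high@pixels[m]
    v <- vncs[[k]]@pixels[m]
    clamped <- clamped + sum(lo < lowRange[1] | lo >= lowRange[2] |
                             hi < highRange[1] | hi >= highRange[2])
    idx <- .binIndex(lo, lowEdges) + nl * (.binIndex(hi, highEdges) - 1L)
    cs <- tabulate(idx, nbins = nl * nh)
    counts <- counts + cs
    sm <- rowsum(v, idx)
    sums[as.integer(rownames(sm))] <- sums[as.integer(rownames(sm))] + sm
  }
  if (total == 0L) stop("no masked pixels in input")
  if (clamped > 0)
    message(sprintf("buildLookup: %d out-of-range sample(s) clamped to edge bins",
                    as.integer(clamped)))
  values <- matrix(NA_real_, nl, nh)
  obs <- counts > 0
  values[obs] <- sums[obs] / counts[obs]
  new("LookupTable", values = values, observed = obs, counts = counts,
      lowEdges = lowEdges, highEdges = highEdges,
      fillValuePolicy = "none", clampedSamples = clamped)
}

#' Impute unobserved lookup cells
#'
#' Iterative penalized-least-squares inpainting: a DCT-domain smoother with
#' a geometrically decreasing smoothing parameter is applied for a fixed
#' number of iterations, re-imposing the observed cells after each step, so
#' observed values are never changed. Because the cosine basis imposes a
#' zero-slope boundary condition that biases extrapolation of tilted
#' surfaces near the table edge, the global linear trend of the observed
#' cells is removed before smoothing and restored afterwards (the VNC
#' lookup surface is close to planar, so the smoother only has to impute
#' the curvature residual). A table with no observed cell at all is filled
#' with zeros.
#'
#' @param table a \linkS4class{LookupTable}.
#' @param nIter number of iterations (default 100).
#' @param sStart,sEnd first and last smoothing parameters of the geometric
#'   schedule (defaults 1e3 and 1e-3).
#' @return the imputed \linkS4class{LookupTable} (all values finite).
#' @export
inpaintLookup <- function(table, nIter = 100L, sStart = 1e3, sEnd = 1e-3) {
  stopifnot(is(table, "LookupTable"))
  if (nIter < 1L) stop("nIter must be >= 1")
  obs <- table@observed
  if (!any(obs)) {
    table@values[] <- 0
    table@fillValuePolicy <- "zero"
    return(table)
  }
  if (all(obs)) {
    table@fillValuePolicy <- "dct-pls"
    return(table)
  }
  v <- table@values
  n1 <- nrow(v); n2 <- ncol(v)
  # remove the least-squares plane through the observed cells
  ii <- matrix(seq_len(n1), n1, n2)
  jj <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  X <- cbind(1, ii[obs], jj[obs])
  qrX <- qr(X)
  beta <- if (qrX$rank == 3L) qr.coef(qrX, v[obs])
          else c(mean(v[obs]), 0, 0)
  trend <- beta[1] + beta[2] * ii + beta[3] * jj
  y <- v - trend; y[!obs] <- 0
  z <- y; z[!obs] <- 0
  lam1 <- 2 - 2 * cos(pi * (0:(n1 - 1)) / n1)
  lam2 <- 2 - 2 * cos(pi * (0:(n2 - 1)) / n2)
  Lam <- outer(lam1, lam2, "+")
  Wm <- obs * 1
  sched <- exp(seq(log(sStart), log(sEnd), length.out = nIter))
  for (s in sched) {
    G <- 1 / (1 + s * Lam^2)
    z <- .idct2(G * .dct2(Wm * (y - z) + z))
    z[obs] <- y[obs]
  }
  z <- z + trend
  z[obs] <- v[obs]
  z[!is.finite(z)] <- 0
  table@values <- z
  table@fillValuePolicy <- "dct-pls"
  table
}

#' Apply a lookup table to a DECT pair
#'
#' Per pixel the output is the table value of the cell containing the
#' (low, high) pair; out-of-range inputs are clamped to the edge bins. The
#' table must be fully imputed (all values finite).
#'
#' @param table an imputed \linkS4class{LookupTable}.
#' @param pair a \linkS4class{DECTPair}.
#' @return an \linkS4class{HUImage} (the raw L-VNC, before median
#'   filtering).
#' @export
applyLookup <- function(table, pair) {
  stopifnot(is(table, "LookupTable"), is(pair, "DECTPair"))
  if (any(!is.finite(table@values)))
    stop("lookup table has non-finite cells; run inpaintLookup first")
  i <- .binIndex(pair@low@pixels, table@lowEdges)
  j <- .binIndex(pair@high@pixels, table@highEdges)
  out <- matrix(table@values[cbind(as.vector(i), as.vector(j))],
                nrow(pair@low@pixels), ncol(pair@low@pixels))
  HUImage(out, sliceId = pair@low@sliceId, subjectId = pair@low@subjectId)
}

#' Median filter an HU image
#'
#' Each pixel is replaced by the median of its kernel x kernel
#' neighborhood; borders use symmetric reflection (the edge pixel is
#' included in the reflection).
#'
#' @param image an \linkS4class{HUImage}.
#' @param kernel odd kernel size (default 5).
#' @return the filtered \linkS4class{HUImage}.
#' @export
medianFilterImage <- function(image, kernel = 5L) {
  stopifnot(is(image, "HUImage"))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be a positive odd integer")
  if (kernel == 1L) return(image)
  HUImage(.nn_median_filter(image@pixels, kernel),
          sliceId = image@sliceId, subjectId = image@subjectId)
}

#' Export the lookup raster as a PNG
#'
#' Renders the lookup image (low-energy HU on x, high-energy HU on y, cell
#' value as gray level).
#'
#' @param table an imputed \linkS4class{LookupTable}.
#' @param path output PNG path.
#' @return invisibly, \code{path}.
#' @export
exportLookupRaster <- function(table, path) {
  v <- table@values
  rng <- range(v, finite = TRUE)
  png(path, width = 600, height = 600)
  on.exit(dev.off())
  graphics::image(x = table@lowEdges[-1], y = table@highEdges[-1],
                  z = v, col = gray(seq(0, 1, length.out = 256)),
                  xlab = "low-energy HU", ylab = "high-energy HU",
                  main = "VNC lookup", zlim = rng, useRaster = TRUE)
  invisible(path)
}
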