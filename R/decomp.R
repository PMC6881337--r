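# Linear three-material decomposition: a documented stand-in for the
# vendor's proprietary VNC software. Per pixel the (low, high) HU pair p is
# written p = w + a*(b - w) + c*d with w the water point, b the hemorrhage
# point and d = (r, 1) the iodine spectral direction; the iodine image is c
# and the scalar VNC blends the iodine-free point q = w + a*(b - w) as
# mu*q_low + (1 - mu)*q_high.

#' Construct a material-decomposition basis
#'
#' The default vendor-style basis places hemorrhage at (68, 62) HU, giving
#' the base materials a small spectral separation; with \code{vncMix} = 0.5
#' a pixel at the hemorrhage point maps to VNC 65. A basis with the
#' hemorrhage point on the low = high diagonal (e.g. \code{c(65, 65)}) is
#' spectrally neutral: it reproduces any spectrally flat tissue exactly
#' (see the methods vignette).
#'
#' @param waterPoint,hemorrhagePoint length-2 (low HU, high HU) points.
#' @param iodineRatio iodine low/high enhancement ratio r.
#' @param vncMix weight of the low-energy coordinate in the scalar VNC.
#' @return a \linkS4class{MaterialBasis}.
#' @export
materialBasis <- function(waterPoint = c(0, 0),
                          hemorrhagePoint = c(68, 62),
                          iodineRatio = 2.12, vncMix = 0.5) {
  new("MaterialBasis", waterPoint = as.numeric(waterPoint),
      hemorrhagePoint = as.numeric(hemorrhagePoint),
      iodineRatio = iodineRatio, vncMix = vncMix)
}

#' A spectrally neutral basis
#'
#' Same VNC value for hemorrhage (65 HU) but with both base materials on
#' the low = high diagonal, so that spectrally flat tissue (low = high = b)
#' decomposes to VNC = b exactly.
#'
#' @param iodineRatio,vncMix as in \code{\link{materialBasis}}.
#' @return a \linkS4class{MaterialBasis}.
#' @export
neutralBasis <- function(iodineRatio = 2.12, vncMix = 0.5) {
  materialBasis(hemorrhagePoint = c(65, 65), iodineRatio = iodineRatio,
                vncMix = vncMix)
}

.basisInverse <- function(basis) {
  e <- basis@hemorrhagePoint - basis@waterPoint
  d <- c(basis@iodineRatio, 1)
  M <- cbind(e, d)
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (abs(det) < 1e-10) stop("singular material basis")
  list(inv = matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / det,
       e = e)
}

#' Three-material decomposition of a DECT pair
#'
#' Solves the 2 x 2 linear system at every pixel and returns the scalar VNC
#' image (the "S-VNC stand-in") and the iodine coefficient image. The
#' decomposition is linear in the input pair and exactly invariant to
#' enhancement along the iodine direction.
#'
#' @param pair a \linkS4class{DECTPair}.
#' @param basis a \linkS4class{MaterialBasis}.
#' @return list with \code{vnc} and \code{iodine} (\linkS4class{HUImage}).
#' @export
decomposeDECT <- function(pair, basis = materialBasis()) {
  stopifnot(is(pair, "DECTPair"), is(basis, "MaterialBasis"))
  bi <- .basisInverse(basis)
  w <- basis@waterPoint
  pl <- pair@low@pixels - w[1]
  ph <- pair@high@pixels - w[2]
  a <- bi$inv[1, 1] * pl + bi$inv[1, 2] * ph
  cc <- bi$inv[2, 1] * pl + bi$inv[2, 2] * ph
  mu <- basis@vncMix
  qLow <- w[1] + a * bi$e[1]
  qHigh <- w[2] + a * bi$e[2]
  vnc <- mu * qLow + (1 - mu) * qHigh
  list(vnc = HUImage(vnc, sliceId = pair@low@sliceId,
                     subjectId = pair@low@subjectId),
       iodine = HUImage(cc, sliceId = pair@low@sliceId,
                        subjectId = pair@low@subjectId))
}

#' Add iodine enhancement along the basis spectral direction
#'
#' low += gain * r * concentration; high += gain * concentration. Used to
#' verify that the decomposition's VNC output is invariant to iodine.
#'
#' @param pair a \linkS4class{DECTPair}.
#' @param concentration non-negative matrix of the pair's shape.
#' @param basis a \linkS4class{MaterialBasis} (supplies r).
#' @param gain positive HU per concentration unit at the high energy.
#' @return the enhanced \linkS4class{DECTPair}.
#' @export
enhanceWithIodine <- function(pair, concentration,
                              basis = materialBasis(), gain = 25) {
  stopifnot(is(pair, "DECTPair"))
  if (gain <= 0) stop("gain must be > 0")
  if (!identical(dim(concentration), dim(pair@low@pixels)))
    stop("concentration shape must match the pair")
  if (any(concentration < 0)) stop("concentration must be non-negative")
  r <- basis@iodineRatio
  low <- HUImage(pair@low@pixels + gain * r * concentration,
                 pair@low@sliceId, pair@low@subjectId)
  high <- HUImage(pair@high@pixels + gain * concentration,
                  pair@high@sliceId, pair@high@subjectId)
  dectPair(low, high, pair@physicsName)
}
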