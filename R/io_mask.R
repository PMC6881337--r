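# Image/mask I/O and mask conditioning (erosion, cropping).

.HU_RANGE_DEFAULT <- c(-1024, 3071)  # 12-bit CT convention

#' Construct an HUImage
#'
#' @param pixels numeric matrix of HU values.
#' @param sliceId,subjectId identifiers.
#' @return an \linkS4class{HUImage}.
#' @export
HUImage <- function(pixels, sliceId = "slice0", subjectId = "subject0") {
  # strip foreign classes/attributes (e.g. nifti images) down to a matrix
  pixels <- matrix(as.double(pixels), nrow(pixels), ncol(pixels))
  new("HUImage", pixels = pixels, sliceId = as.character(sliceId),
      subjectId = as.character(subjectId))
}

#' Construct a BrainMask
#'
#' @param pixels logical matrix (numeric input is coerced via != 0).
#' @return a \linkS4class{BrainMask}.
#' @export
brainMask <- function(pixels) {
  if (!is.logical(pixels)) pixels <- pixels != 0
  new("BrainMask", pixels = pixels)
}

.idsFromPath <- function(path) {
  base <- sub("\\.(nii\\.gz|nii|rds)$", "", basename(path))
  sub <- if (grepl("sub-[A-Za-z0-9]+", base))
    regmatches(base, regexpr("sub-[A-Za-z0-9]+", base)) else base
  slc <- if (grepl("slice-[A-Za-z0-9]+", base))
    regmatches(base, regexpr("slice-[A-Za-z0-9]+", base)) else "slice0"
  list(subject = sub, slice = slc)
}

.clampPixels <- function(p, huRange) {
  n <- sum(p < huRange[1] | p > huRange[2])
  if (n > 0) {
    warning(sprintf("%d pixel(s) outside HU range [%g, %g] were clamped",
                    n, huRange[1], huRange[2]))
    p <- pmin(pmax(p, huRange[1]), huRange[2])
  }
  p
}

#' Read an HU image from disk
#'
#' Supported formats: NIfTI (".nii", ".nii.gz"; 2-D images or 3-D volumes,
#' in which case \code{sliceIndex} selects an axial slice, 1-based) and the
#' package's lossless array archive (".rds" with elements \code{pixels} and
#' optionally \code{subject_id} / \code{slice_id}). Non-finite values are
#' rejected; values outside \code{huRange} are clamped with a warning.
#'
#' @param path file to read.
#' @param sliceIndex 1-based axial slice for 3-D volumes.
#' @param huRange length-2 clamping range in HU.
#' @return an \linkS4class{HUImage}.
#' @export
readHUImage <- function(path, sliceIndex = NULL,
                        huRange = .HU_RANGE_DEFAULT) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- .idsFromPath(path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    vol <- tryCatch(as.array(RNifti::readNifti(path)),
                    error = function(e) stop("unreadable NIfTI: ", path,
                                             " (", conditionMessage(e), ")"))
    if (length(dim(vol)) == 3L) {
      if (is.null(sliceIndex))
        stop("3-D volume requires a sliceIndex")
      if (sliceIndex < 1L || sliceIndex > dim(vol)[3])
        stop("sliceIndex out of range")
      p <- vol[, , sliceIndex]
      ids$slice <- sprintf("slice%d", as.integer(sliceIndex))
    } else if (length(dim(vol)) == 2L) {
      p <- vol
    } else stop("payload is not 2-D and no usable sliceIndex")
  } else if (grepl("\\.rds$", path)) {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$pixels))
      stop("archive lacks a 'pixels' element: ", path)
    p <- obj$pixels
    if (!is.null(obj$subject_id)) ids$subject <- obj$subject_id
    if (!is.null(obj$slice_id)) ids$slice <- obj$slice_id
    if (!is.null(sliceIndex)) {
      if (length(dim(p)) == 3L) p <- p[, , sliceIndex]
    }
  } else stop("unsupported format: ", path)
  if (length(dim(p)) != 2L) stop("payload is not 2-D")
  if (any(!is.finite(p))) stop("non-finite pixel values in ", path)
  p <- .clampPixels(p, huRange)
  HUImage(p, sliceId = ids$slice, subjectId = ids$subject)
}

#' Write an HU image to disk
#'
#' NIfTI output uses a double-precision datatype so that
#' \code{\link{readHUImage}} recovers bit-identical pixel values; ".rds"
#' writes the package's array archive (elements \code{pixels},
#' \code{subject_id}, \code{slice_id}, optionally \code{mask}).
#'
#' @param image an \linkS4class{HUImage}.
#' @param path destination (".nii", ".nii.gz" or ".rds").
#' @param mask optional \linkS4class{BrainMask} stored alongside in the
#'   archive format.
#' @return invisibly, \code{path}.
#' @export
writeHUImage <- function(image, path, mask = NULL) {
  stopifnot(is(image, "HUImage"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(image@pixels, path, datatype = "double")
  } else if (grepl("\\.rds$", path)) {
    obj <- list(pixels = image@pixels, subject_id = image@subjectId,
                slice_id = image@sliceId)
    if (!is.null(mask)) obj$mask <- mask@pixels
    saveRDS(obj, path)
  } else stop("unsupported format: ", path)
  invisible(path)
}

#' Read a brain mask from an array archive
#'
#' @param path ".rds" archive containing a \code{mask} (or \code{pixels})
#'   element.
#' @return a \linkS4class{BrainMask}.
#' @export
readBrainMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  m <- if (is.list(obj)) (if (!is.null(obj$mask)) obj$mask else obj$pixels)
       else obj
  brainMask(m)
}

#' Erode a brain mask with a disk structuring element
#'
#' Morphological erosion by a disk of the given diameter: the set of integer
#' offsets at Euclidean distance <= (diameter - 1)/2 from the center.
#' Pixels whose disk neighborhood extends beyond the raster or touches a
#' false pixel are cleared, so the output true-set is always a subset of the
#' input true-set.
#'
#' @param mask a \linkS4class{BrainMask}.
#' @param diameter odd positive integer (default 5).
#' @return the eroded \linkS4class{BrainMask}.
#' @export
erodeMask <- function(mask, diameter = 5L) {
  stopifnot(is(mask, "BrainMask"))
  diameter <- as.integer(diameter)
  if (diameter < 1L || diameter %% 2L == 0L)
    stop("diameter must be a positive odd integer")
  r <- (diameter - 1L) %/% 2L
  m <- mask@pixels
  if (r == 0L) return(mask)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L * r, W + 2L * r)
  pad[(r + 1L):(r + H), (r + 1L):(r + W)] <- m
  out <- matrix(TRUE, H, W)
  for (di in -r:r) for (dj in -r:r) {
    if (di * di + dj * dj > r * r) next
    out <- out & pad[(r + 1L + di):(r + H + di),
                     (r + 1L + dj):(r + W + dj)]
  }
  brainMask(out)
}

#' Crop an image and mask to the mask bounding box
#'
#' Both rasters are cropped to the tight bounding box of the mask's true
#' pixels, expanded by \code{margin} and clipped to the raster bounds; pixel
#' values are preserved.
#'
#' @param image an \linkS4class{HUImage}.
#' @param mask a non-empty \linkS4class{BrainMask} of the same shape.
#' @param margin non-negative integer bounding-box expansion.
#' @return list with elements \code{image} and \code{mask}.
#' @export
cropToMask <- function(image, mask, margin = 0L) {
  stopifnot(is(image, "HUImage"), is(mask, "BrainMask"))
  if (!identical(dim(image@pixels), dim(mask@pixels)))
    stop("image and mask shapes differ")
  if (!any(mask@pixels)) stop("mask is empty")
  margin <- as.integer(margin)
  if (margin < 0L) stop("margin must be non-negative")
  idx <- which(mask@pixels, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - margin)
  r1 <- min(nrow(mask@pixels), max(idx[, 1]) + margin)
  c0 <- max(1L, min(idx[, 2]) - margin)
  c1 <- min(ncol(mask@pixels), max(idx[, 2]) + margin)
  list(image = HUImage(image@pixels[r0:r1, c0:c1, drop = FALSE],
                       sliceId = image@sliceId,
                       subjectId = image@subjectId),
       mask = brainMask(mask@pixels[r0:r1, c0:c1, drop = FALSE]))
}
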