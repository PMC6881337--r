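# Generics and accessors.

#' Pixel data of an image or mask
#' @param x an \linkS4class{HUImage} or \linkS4class{BrainMask}.
#' @return numeric (HUImage) or logical (BrainMask) matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "HUImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BrainMask", function(x) x@pixels)

#' Slice and subject identifiers
#' @param x an \linkS4class{HUImage}.
#' @return character scalar.
#' @export
setGeneric("sliceId", function(x) standardGeneric("sliceId"))

#' @rdname sliceId
#' @export
setMethod("sliceId", "HUImage", function(x) x@sliceId)

#' @rdname sliceId
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname sliceId
#' @export
setMethod("subjectId", "HUImage", function(x) x@subjectId)

#' @rdname sliceId
#' @export
setMethod("subjectId", "PhantomScene", function(x) x@subjectId)

#' Component images of a DECT pair
#' @param x a \linkS4class{DECTPair}.
#' @return an \linkS4class{HUImage} (or the physics label for
#'   \code{physicsName}).
#' @export
setGeneric("lowImage", function(x) standardGeneric("lowImage"))

#' @rdname lowImage
#' @export
setMethod("lowImage", "DECTPair", function(x) x@low)

#' @rdname lowImage
#' @export
setGeneric("highImage", function(x) standardGeneric("highImage"))

#' @rdname lowImage
#' @export
setMethod("highImage", "DECTPair", function(x) x@high)

#' @rdname lowImage
#' @export
setGeneric("physicsName", function(x) standardGeneric("physicsName"))

#' @rdname lowImage
#' @export
setMethod("physicsName", "DECTPair", function(x) x@physicsName)

#' Scene accessors
#' @param x a \linkS4class{PhantomScene}.
#' @return labels matrix, \linkS4class{BrainMask}, or iodine map.
#' @export
setGeneric("sceneLabels", function(x) standardGeneric("sceneLabels"))

#' @rdname sceneLabels
#' @export
setMethod("sceneLabels", "PhantomScene", function(x) x@labels)

#' @rdname sceneLabels
#' @export
setGeneric("sceneMask", function(x) standardGeneric("sceneMask"))

#' @rdname sceneLabels
#' @export
setMethod("sceneMask", "PhantomScene", function(x) x@mask)

#' @rdname sceneLabels
#' @export
setGeneric("iodineMap", function(x) standardGeneric("iodineMap"))

#' @rdname sceneLabels
#' @export
setMethod("iodineMap", "PhantomScene", function(x) x@iodineMap)

#' Lookup-table accessors
#' @param x a \linkS4class{LookupTable}.
#' @return cell values, observed flags, counts, or bin edges.
#' @export
setGeneric("lookupValues", function(x) standardGeneric("lookupValues"))

#' @rdname lookupValues
#' @export
setMethod("lookupValues", "LookupTable", function(x) x@values)

#' @rdname lookupValues
#' @export
setGeneric("lookupObserved", function(x) standardGeneric("lookupObserved"))

#' @rdname lookupValues
#' @export
setMethod("lookupObserved", "LookupTable", function(x) x@observed)

#' @rdname lookupValues
#' @export
setGeneric("lookupCounts", function(x) standardGeneric("lookupCounts"))

#' @rdname lookupValues
#' @export
setMethod("lookupCounts", "LookupTable", function(x) x@counts)

#' Network parameter access
#'
#' Parameters are a flat named list of numeric arrays; names follow the
#' layer inventory ("conv_in.wt", "blk3.conv2.wt", "conv_out.b", ...).
#'
#' @param x a \linkS4class{ResidualNet}.
#' @param value replacement parameter list (same names and shapes).
#' @return the parameter list.
#' @export
setGeneric("netParams", function(x) standardGeneric("netParams"))

#' @rdname netParams
#' @export
setMethod("netParams", "ResidualNet", function(x) x@params)

#' @rdname netParams
#' @export
setGeneric("netParams<-", function(x, value) standardGeneric("netParams<-"))

#' @rdname netParams
#' @export
setMethod("netParams<-", "ResidualNet", function(x, value) {
  stopifnot(identical(sort(names(value)), sort(names(x@params))))
  x@params <- value[names(x@params)]
  x
})

#' @describeIn pixels shape of the pixel raster
#' @export
setMethod("dim", "HUImage", function(x) dim(x@pixels))

#' @describeIn pixels shape of the mask raster
#' @export
setMethod("dim", "BrainMask", function(x) dim(x@pixels))

setMethod("show", "HUImage", function(object) {
  p <- object@pixels
  cat(sprintf("HUImage %dx%d [subject=%s slice=%s] HU range [%.1f, %.1f]\n",
              nrow(p), ncol(p), object@subjectId, object@sliceId,
              min(p), max(p)))
})

setMethod("show", "BrainMask", function(object) {
  p <- object@pixels
  cat(sprintf("BrainMask %dx%d (%d true pixels, %.1f%%)\n",
              nrow(p), ncol(p), sum(p), 100 * mean(p)))
})

setMethod("show", "DECTPair", function(object) {
  cat(sprintf("DECTPair [%s] %dx%d subject=%s slice=%s\n",
              object@physicsName, nrow(object@low@pixels),
              ncol(object@low@pixels), object@low@subjectId,
              object@low@sliceId))
})

setMethod("show", "PhantomScene", function(object) {
  tab <- table(factor(object@labels, levels = 0:4,
                      labels = c("background", "csf", "white", "gray",
                                 "hemorrhage")))
  cat(sprintf("PhantomScene %dx%d subject=%s seed=%d\n",
              nrow(object@labels), ncol(object@labels), object@subjectId,
              object@seed))
  print(tab)
})

setMethod("show", "LookupTable", function(object) {
  cat(sprintf(
    "LookupTable %dx%d cells, %.1f%% observed, %s imputation, %d clamped\n",
    nrow(object@values), ncol(object@values), 100 * mean(object@observed),
    object@fillValuePolicy, as.integer(object@clampedSamples)))
})

setMethod("show", "ResidualNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ResidualNet [%s] %d groups x %d blocks, dilations %s, %d channels, %d params\n",
    cfg@profile, cfg@groups, cfg@blocksPerGroup,
    paste(cfg@dilations, collapse = "/"), cfg@channels,
    sum(vapply(object@params, length, 1L))))
})

setMethod("show", "TrainingHistory", function(object) {
  cat(sprintf(
    "TrainingHistory: %d epochs (%s), best val %.3f HU at epoch %d\n",
    object@epochsRun, object@stopReason, min(object@valLoss),
    object@bestEpoch))
})
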