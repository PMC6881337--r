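# S4 containers for the DECT post-processing pipeline.

#' HUImage: a 2-D raster of Hounsfield-unit values
#'
#' The universal pixel-data carrier of the package: TNC, S-VNC, L-VNC, DNC
#' and difference maps are all \code{HUImage} objects. Pixels are stored as a
#' numeric matrix in (row, col) order; every value must be finite.
#'
#' @slot pixels numeric matrix of HU values.
#' @slot sliceId character scalar identifying the slice.
#' @slot subjectId character scalar; the patient/scene grouping key.
#' @aliases HUImage
#' @exportClass HUImage
setClass("HUImage",
  representation(pixels = "matrix", sliceId = "character",
                 subjectId = "character"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be numeric")
    if (nrow(p) < 1L || ncol(p) < 1L) return("pixels must be non-empty")
    if (any(!is.finite(p))) return("pixels must all be finite")
    if (length(object@sliceId) != 1L || length(object@subjectId) != 1L)
      return("sliceId and subjectId must be length-1 character")
    TRUE
  })

#' BrainMask: a binary raster marking intracranial parenchyma
#'
#' All losses and similarity metrics in the package are restricted to the
#' true pixels of a \code{BrainMask} with the same shape as its companion
#' \linkS4class{HUImage}.
#'
#' @slot pixels logical matrix.
#' @aliases BrainMask
#' @exportClass BrainMask
setClass("BrainMask",
  representation(pixels = "matrix"),
  validity = function(object) {
    p <- object@pixels
    if (!is.logical(p)) return("mask pixels must be logical")
    if (nrow(p) < 1L || ncol(p) < 1L) return("mask must be non-empty")
    if (any(is.na(p))) return("mask must not contain NA")
    TRUE
  })

#' DECTPair: aligned low- and high-energy HU images
#'
#' @slot low,high \linkS4class{HUImage} objects of identical shape and
#'   identical subject/slice identifiers.
#' @slot physicsName label of the acquisition physics (e.g. "80/150Sn").
#' @aliases DECTPair
#' @exportClass DECTPair
setClass("DECTPair",
  representation(low = "HUImage", high = "HUImage",
                 physicsName = "character"),
  validity = function(object) {
    if (!identical(dim(object@low@pixels), dim(object@high@pixels)))
      return("low and high images must have identical shape")
    if (!identical(object@low@subjectId, object@high@subjectId) ||
        !identical(object@low@sliceId, object@high@sliceId))
      return("low and high images must share subject and slice identifiers")
    if (length(object@physicsName) != 1L)
      return("physicsName must be a length-1 character")
    TRUE
  })

#' PhantomScene: ground-truth tissue scene for the DECT simulator
#'
#' Tissue classes are coded 0 = background, 1 = CSF, 2 = white matter,
#' 3 = gray matter, 4 = hemorrhage. The brain mask is the non-background
#' region and the iodine concentration map (arbitrary units, >= 0) is zero
#' outside it.
#'
#' @slot labels integer matrix of tissue-class codes.
#' @slot baseHU named numeric: mean HU per tissue class.
#' @slot iodineMap numeric matrix of iodine concentration (>= 0).
#' @slot mask \linkS4class{BrainMask}; equals labels != background.
#' @slot subjectId character scene/patient identifier.
#' @slot seed integer seed the scene was generated from.
#' @aliases PhantomScene
#' @exportClass PhantomScene
setClass("PhantomScene",
  representation(labels = "matrix", baseHU = "numeric", iodineMap = "matrix",
                 mask = "BrainMask", subjectId = "character",
                 seed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@labels), dim(object@iodineMap)))
      return("labels and iodineMap must have identical shape")
    if (!identical(dim(object@labels), dim(object@mask@pixels)))
      return("labels and mask must have identical shape")
    if (any(object@iodineMap < 0)) return("iodineMap must be non-negative")
    if (any(object@iodineMap[!object@mask@pixels] != 0))
      return("iodineMap must be zero outside the brain mask")
    if (!identical(unname(object@mask@pixels),
                   unname(object@labels != 0L)))
      return("mask must equal (labels != background)")
    if (!all(c("background", "csf", "white", "gray", "hemorrhage") %in%
             names(object@baseHU)))
      return("baseHU must name all five tissue classes")
    TRUE
  })

#' PhysicsConfig: named DECT acquisition physics for the simulator
#'
#' @slot name configuration label (e.g. "80/150Sn", "100/150Sn").
#' @slot iodineRatio iodine low/high-energy HU enhancement ratio (> 0).
#' @slot iodineHighGain HU enhancement at the high energy per unit iodine
#'   concentration (> 0).
#' @slot tiltLow,tiltHigh named numeric per-class spectral HU offsets at the
#'   low and high energy (small, a few HU).
#' @slot noiseSigmaLow,noiseSigmaHigh additive Gaussian noise SD in HU.
#' @aliases PhysicsConfig
#' @exportClass PhysicsConfig
setClass("PhysicsConfig",
  representation(name = "character", iodineRatio = "numeric",
                 iodineHighGain = "numeric", tiltLow = "numeric",
                 tiltHigh = "numeric", noiseSigmaLow = "numeric",
                 noiseSigmaHigh = "numeric"),
  validity = function(object) {
    if (object@iodineRatio <= 0) return("iodineRatio must be > 0")
    if (object@iodineHighGain <= 0) return("iodineHighGain must be > 0")
    if (object@noiseSigmaLow < 0 || object@noiseSigmaHigh < 0)
      return("noise sigmas must be >= 0")
    TRUE
  })

#' MaterialBasis: linear three-material decomposition basis
#'
#' Defines the two base materials (water, hemorrhage) as points in the
#' (low HU, high HU) plane plus the iodine spectral direction (r, 1). The
#' scalar VNC output blends the projected point's two energy coordinates
#' with weight \code{vncMix} on the low-energy coordinate.
#'
#' @slot waterPoint,hemorrhagePoint numeric length-2 (low HU, high HU).
#' @slot iodineRatio iodine low/high enhancement ratio r (> 0).
#' @slot vncMix weight of the low-energy coordinate in [0, 1].
#' @aliases MaterialBasis
#' @exportClass MaterialBasis
setClass("MaterialBasis",
  representation(waterPoint = "numeric", hemorrhagePoint = "numeric",
                 iodineRatio = "numeric", vncMix = "numeric"),
  validity = function(object) {
    if (length(object@waterPoint) != 2L ||
        length(object@hemorrhagePoint) != 2L)
      return("waterPoint and hemorrhagePoint must be length-2")
    if (object@iodineRatio <= 0) return("iodineRatio must be > 0")
    if (object@vncMix < 0 || object@vncMix > 1)
      return("vncMix must lie in [0, 1]")
    e <- object@hemorrhagePoint - object@waterPoint
    d <- c(object@iodineRatio, 1)
    if (abs(e[1] * d[2] - e[2] * d[1]) < 1e-8)
      return(paste("degenerate basis: iodine direction parallel to the",
                   "water-hemorrhage axis"))
    TRUE
  })

#' LookupTable: 2-D (low, high) HU to VNC intensity lookup
#'
#' Cells are indexed (low-bin, high-bin); observed cells hold the running
#' mean of the VNC values of the training pixels that fell into them, and
#' the observed/counts rasters record coverage. After inpainting every cell
#' value is finite.
#'
#' @slot values numeric matrix (low-bin x high-bin) of VNC values; NA in
#'   unobserved cells until \code{\link{inpaintLookup}} is applied.
#' @slot observed logical matrix; TRUE iff counts > 0.
#' @slot counts numeric matrix of per-cell sample counts.
#' @slot lowEdges,highEdges strictly increasing bin-edge vectors (HU).
#' @slot fillValuePolicy label of the imputation applied ("none",
#'   "dct-pls", "zero").
#' @slot clampedSamples number of out-of-range samples clamped to edge bins.
#' @aliases LookupTable
#' @exportClass LookupTable
setClass("LookupTable",
  representation(values = "matrix", observed = "matrix", counts = "matrix",
                 lowEdges = "numeric", highEdges = "numeric",
                 fillValuePolicy = "character", clampedSamples = "numeric"),
  validity = function(object) {
    nl <- length(object@lowEdges) - 1L
    nh <- length(object@highEdges) - 1L
    if (nl < 1L || nh < 1L) return("need >= 2 edges per axis")
    if (any(diff(object@lowEdges) <= 0) || any(diff(object@highEdges) <= 0))
      return("bin edges must be strictly increasing")
    if (!identical(dim(object@values), c(nl, nh)))
      return("values shape must match bin counts")
    if (!identical(dim(object@observed), c(nl, nh)) ||
        !identical(dim(object@counts), c(nl, nh)))
      return("observed/counts shape must match values")
    if (!identical(unname(object@observed), unname(object@counts > 0)))
      return("observed must equal (counts > 0)")
    TRUE
  })

#' NetworkConfig: residual-network architecture and training settings
#'
#' The default ("clinical") profile mirrors the clinical-scale settings
#' (64 channels, 256 x 256 inputs, learning rate 1e-5, dropout 0.5); the
#' "desk" profile is a small CPU-scale variant (8 channels, 64 x 64).
#'
#' @slot groups number of residual-block groups.
#' @slot blocksPerGroup residual blocks per group.
#' @slot dilations integer dilation per group (length = groups).
#' @slot channels feature channels inside the network.
#' @slot kernel convolution kernel size (odd).
#' @slot dropoutRate dropout probability in [0, 1).
#' @slot weightDecay L2 penalty coefficient on convolution weights.
#' @slot learningRate Adam learning rate.
#' @slot batchSize training batch size.
#' @slot inputSize working spatial resolution (images are resampled to
#'   inputSize x inputSize).
#' @slot normalization "batch" or "none".
#' @slot profile profile label ("clinical" or "desk").
#' @aliases NetworkConfig
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(groups = "integer", blocksPerGroup = "integer",
                 dilations = "integer", channels = "integer",
                 kernel = "integer", dropoutRate = "numeric",
                 weightDecay = "numeric", learningRate = "numeric",
                 batchSize = "integer", inputSize = "integer",
                 normalization = "character", profile = "character"),
  validity = function(object) {
    if (length(object@dilations) != object@groups)
      return("need one dilation per group")
    if (any(object@dilations < 1L)) return("dilations must be >= 1")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      return("dropoutRate must lie in [0, 1)")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@kernel %% 2L != 1L) return("kernel must be odd")
    if (!object@normalization %in% c("batch", "none"))
      return("normalization must be 'batch' or 'none'")
    TRUE
  })

#' ResidualNet: a built residual network (parameters + state)
#'
#' @slot config \linkS4class{NetworkConfig}.
#' @slot params flat named list of parameter arrays (convolution weights /
#'   biases, normalization scales / shifts).
#' @slot state flat named list of non-trained state (batch-norm running
#'   moments).
#' @slot seed integer initialization seed.
#' @aliases ResidualNet
#' @exportClass ResidualNet
setClass("ResidualNet",
  representation(config = "NetworkConfig", params = "list", state = "list",
                 seed = "integer"))

#' TrainingSample: one network input/target pair
#'
#' @slot input numeric array (size, size, 3): normalized low, high and
#'   median-filtered L-VNC channels.
#' @slot target numeric matrix (size, size): TNC minus L-VNC, in HU.
#' @slot mask \linkS4class{BrainMask} at the working resolution.
#' @slot subjectId,sliceId identifiers.
#' @aliases TrainingSample
#' @exportClass TrainingSample
setClass("TrainingSample",
  representation(input = "array", target = "matrix", mask = "BrainMask",
                 subjectId = "character", sliceId = "character"),
  validity = function(object) {
    d <- dim(object@input)
    if (length(d) != 3L || d[3] != 3L)
      return("input must be a (size, size, 3) array")
    if (!identical(dim(object@target), d[1:2]))
      return("target shape must match input")
    if (!identical(dim(object@mask@pixels), d[1:2]))
      return("mask shape must match input")
    if (!any(object@mask@pixels)) return("mask must be non-empty")
    TRUE
  })

#' TrainingHistory: per-epoch losses of a training run
#'
#' @slot trainLoss,valLoss per-epoch masked RMSE (HU).
#' @slot epochsRun number of epochs actually run.
#' @slot bestEpoch epoch of the best validation loss.
#' @slot stopReason "plateau" or "max_epochs".
#' @slot seed training seed.
#' @aliases TrainingHistory
#' @exportClass TrainingHistory
setClass("TrainingHistory",
  representation(trainLoss = "numeric", valLoss = "numeric",
                 epochsRun = "integer", bestEpoch = "integer",
                 stopReason = "character", seed = "integer"),
  validity = function(object) {
    if (length(object@trainLoss) != object@epochsRun ||
        length(object@valLoss) != object@epochsRun)
      return("loss vectors must have length epochsRun")
    if (any(!is.finite(object@trainLoss)) || any(!is.finite(object@valLoss)))
      return("losses must be finite")
    TRUE
  })
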