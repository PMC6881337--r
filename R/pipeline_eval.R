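# DNC composition, brain-masked similarity metrics (batched RMSE and
# Spearman rank correlation) and the end-to-end pipeline driver.

#' Compose a deep non-contrast image
#'
#' Pixelwise sum of the L-VNC image and a predicted difference map; exact,
#' no clipping.
#'
#' @param lvnc,diff \linkS4class{HUImage}s of identical shape.
#' @return the DNC \linkS4class{HUImage}.
#' @export
composeDNC <- function(lvnc, diff) {
  if (!identical(dim(lvnc@pixels), dim(diff@pixels)))
    stop("shape mismatch")
  HUImage(lvnc@pixels + diff@pixels, sliceId = lvnc@sliceId,
          subjectId = lvnc@subjectId)
}

.maskedValues <- function(a, b, mask) {
  if (!identical(dim(a@pixels), dim(b@pixels)) ||
      !identical(dim(a@pixels), dim(mask@pixels)))
    stop("shape mismatch")
  if (!any(mask@pixels)) stop("empty mask")
  list(a = a@pixels[mask@pixels], b = b@pixels[mask@pixels])
}

#' Masked root mean squared error
#'
#' sqrt(mean over masked pixels of (a - b)^2), in HU.
#'
#' @param a,b \linkS4class{HUImage}s of identical shape.
#' @param mask a non-empty \linkS4class{BrainMask}.
#' @return non-negative scalar.
#' @export
maskedRMSE <- function(a, b, mask) {
  v <- .maskedValues(a, b, mask)
  sqrt(mean((v$a - v$b)^2))
}

# Average ranks (ties get the mean of the ranks they span).
.avgRank <- function(x) rank(x, ties.method = "average")

.spearmanFromValues <- function(a, b) {
  if (length(a) < 3L) stop("need >= 3 masked pixels")
  ra <- .avgRank(a); rb <- .avgRank(b)
  ra <- ra - mean(ra); rb <- rb - mean(rb)
  den <- sqrt(sum(ra^2) * sum(rb^2))
  if (den == 0) stop("zero variance in ranks (all values tied)")
  sum(ra * rb) / den
}

#' Masked Spearman rank correlation
#'
#' Pearson correlation of the average-ranked masked values of the two
#' images (ties receive average ranks). Invariant under strictly monotone
#' transforms of either input.
#'
#' @param a,b \linkS4class{HUImage}s of identical shape.
#' @param mask a \linkS4class{BrainMask} with at least 3 true pixels.
#' @return correlation in [-1, 1].
#' @export
maskedSpearman <- function(a, b, mask) {
  v <- .maskedValues(a, b, mask)
  .spearmanFromValues(v$a, v$b)
}

#' Batched similarity metrics
#'
#' Images are shuffled with the given seed and partitioned into consecutive
#' batches of \code{batchSize} (the last, smaller batch is dropped unless
#' \code{keepPartial}); each batch's RMSE and Spearman correlation are
#' computed over the pooled masked voxels of its images, stratifying the
#' metrics by brain-voxel count.
#'
#' @param preds,refs,masks aligned lists of images and masks.
#' @param batchSize images per batch (default 32).
#' @param seed shuffle seed.
#' @param comparison label stored in the records (e.g. "DNC-vs-TNC").
#' @param keepPartial keep the final incomplete batch.
#' @return data.frame with columns batch_id, comparison, rmse,
#'   spearman_rho, n_voxels.
#' @export
batchedMetrics <- function(preds, refs, masks, batchSize = 32L, seed = 1L,
                           comparison = "DNC-vs-TNC",
                           keepPartial = FALSE) {
  n <- length(preds)
  if (n == 0L) stop("empty image lists")
  if (length(refs) != n || length(masks) != n)
    stop("preds, refs and masks must be aligned")
  if (batchSize < 1L) stop("batchSize must be >= 1")
  perm <- withSeed(seed, sample.int(n))
  nBatch <- if (keepPartial) ceiling(n / batchSize) else n %/% batchSize
  if (nBatch == 0L)
    stop("fewer images than one batch; reduce batchSize or keepPartial")
  out <- vector("list", nBatch)
  for (bi in seq_len(nBatch)) {
    idx <- perm[((bi - 1L) * batchSize + 1L):min(bi * batchSize, n)]
    av <- bv <- numeric(0)
    for (i in idx) {
      v <- .maskedValues(preds[[i]], refs[[i]], masks[[i]])
      av <- c(av, v$a); bv <- c(bv, v$b)
    }
    out[[bi]] <- data.frame(
      batch_id = bi, comparison = comparison,
      rmse = sqrt(mean((av - bv)^2)),
      spearman_rho = .spearmanFromValues(av, bv),
      n_voxels = length(av), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pipeline configuration
#'
#' @param nScenes number of synthetic patients.
#' @param height,width scene raster size.
#' @param physicsName physics preset ("80/150Sn" or "100/150Sn").
#' @param splitFractions train/validation/test fractions.
#' @param seed master seed for every stage.
#' @param tncNoiseSigma TNC noise SD (HU).
#' @param tncOffset per-class TNC spectral offset (the anatomy-dependent
#'   discrepancy the network learns; \code{\link{defaultTNCOffset}}).
#' @param basis \linkS4class{MaterialBasis} for the S-VNC stand-in.
#' @param lowRange,highRange,binWidth lookup bin geometry.
#' @param inpaintIter lookup inpainting iterations.
#' @param erodeDiameter brain-mask erosion diameter (pixels).
#' @param medianKernel L-VNC median-filter kernel (pixels).
#' @param network \linkS4class{NetworkConfig}.
#' @param patience,maxEpochs early-stopping settings.
#' @param evalBatchSize images per metric batch.
#' @param keepPartialBatch keep the final incomplete metric batch.
#' @param sceneParams scene-generation parameters.
#' @param outDir optional directory for the CSV/JSON report.
#' @return configuration list for \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(nScenes = 200L, height = 64L, width = 64L,
                           physicsName = "80/150Sn",
                           splitFractions = c(0.745, 0.145, 0.110),
                           seed = 1L, tncNoiseSigma = 2,
                           tncOffset = defaultTNCOffset(),
                           basis = materialBasis(),
                           lowRange = c(-200, 400),
                           highRange = c(-200, 400), binWidth = 1,
                           inpaintIter = 100L, erodeDiameter = 5L,
                           medianKernel = 5L,
                           network = networkConfig("desk"),
                           patience = 3L, maxEpochs = 12L,
                           evalBatchSize = 8L, keepPartialBatch = FALSE,
                           sceneParams = dectdnc::sceneParams(),
                           outDir = NULL) {
  as.list(environment())
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.summarizeBatches <- function(records) {
  agg <- split(records, records$comparison)
  do.call(rbind, lapply(agg, function(df) {
    nb <- nrow(df)
    ci <- function(x) qnorm(0.975) * sd(x) / sqrt(length(x))
    data.frame(comparison = df$comparison[1], n_batches = nb,
               rmse_mean = mean(df$rmse),
               rmse_ci95 = if (nb > 1) ci(df$rmse) else NA_real_,
               spearman_mean = mean(df$spearman_rho),
               spearman_ci95 = if (nb > 1) ci(df$spearman_rho) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full synthetic DECT-to-DNC pipeline
#'
#' Stages: simulate the dataset; decompose every pair into the S-VNC
#' stand-in; build and inpaint the lookup table from the training
#' partition; apply it (plus median filtering) to all partitions to form
#' L-VNC images; train the residual network on the training partition with
#' early stopping on the validation partition; predict differences and
#' compose DNC images on the held-out test partition; compute batched
#' RMSE/Spearman metrics for DNC, L-VNC and S-VNC against TNC. All metrics
#' are evaluated at the network's working resolution inside the eroded
#' brain mask. Deterministic given the configuration seed.
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @return list with \code{records} (per-batch metric data.frame),
#'   \code{summary} (per-comparison mean and 95\% CI), \code{history}
#'   (\linkS4class{TrainingHistory}), \code{valPlateau} (best validation
#'   loss, HU) and \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cfg <- config
  physics <- .stage("physics", physicsConfig(cfg$physicsName))
  seeds <- deriveSeeds(cfg$seed, 4L)

  ds <- .stage("simulate", makeDataset(
    cfg$nScenes, cfg$splitFractions, physics, seeds[1], cfg$height,
    cfg$width, tncNoiseSigma = cfg$tncNoiseSigma,
    tncOffset = cfg$tncOffset, params = cfg$sceneParams))

  slices <- .stage("decompose", lapply(ds$slices, function(sl) {
    dec <- decomposeDECT(sl$pair, cfg$basis)
    sl$svnc <- dec$vnc
    sl$emask <- erodeMask(sl$mask, cfg$erodeDiameter)
    sl
  }))
  part <- ds$manifest$partition
  trainIdx <- which(part == "train")
  valIdx <- which(part == "validation")
  testIdx <- which(part == "test")

  lut <- .stage("build-lookup", {
    tb <- buildLookup(lapply(slices[trainIdx], `[[`, "pair"),
                      lapply(slices[trainIdx], `[[`, "svnc"),
                      lapply(slices[trainIdx], `[[`, "emask"),
                      cfg$lowRange, cfg$highRange, cfg$binWidth)
    inpaintLookup(tb, cfg$inpaintIter)
  })

  slices <- .stage("lvnc", lapply(slices, function(sl) {
    sl$lvnc <- medianFilterImage(applyLookup(lut, sl$pair),
                                 cfg$medianKernel)
    sl
  }))

  size <- cfg$network@inputSize
  samples <- .stage("samples", lapply(slices, function(sl)
    makeTrainingSamples(sl$pair, sl$lvnc, sl$tnc, sl$emask, size)))

  trained <- .stage("train", {
    net <- buildNetwork(cfg$network, seeds[2])
    trainModel(net, samples[trainIdx], samples[valIdx],
               patience = cfg$patience, maxEpochs = cfg$maxEpochs,
               seed = seeds[3])
  })

  evalSets <- .stage("predict", {
    dncs <- list(); lvncs <- list(); svncs <- list(); tncs <- list()
    emasks <- list()
    for (j in seq_along(testIdx)) {
      i <- testIdx[j]
      sm <- samples[[i]]
      diff <- predictDifference(trained$model, sm)
      lvncD <- HUImage(.downsample(slices[[i]]$lvnc@pixels, size),
                       sm@sliceId, sm@subjectId)
      dncs[[j]] <- composeDNC(lvncD, diff)
      lvncs[[j]] <- lvncD
      svncs[[j]] <- HUImage(.downsample(slices[[i]]$svnc@pixels, size),
                            sm@sliceId, sm@subjectId)
      tncs[[j]] <- HUImage(.downsample(slices[[i]]$tnc@pixels, size),
                           sm@sliceId, sm@subjectId)
      emasks[[j]] <- sm@mask
    }
    list(dnc = dncs, lvnc = lvncs, svnc = svncs, tnc = tncs,
         mask = emasks)
  })

  records <- .stage("metrics", {
    rbind(
      batchedMetrics(evalSets$dnc, evalSets$tnc, evalSets$mask,
                     cfg$evalBatchSize, seeds[4], "DNC-vs-TNC",
                     cfg$keepPartialBatch),
      batchedMetrics(evalSets$lvnc, evalSets$tnc, evalSets$mask,
                     cfg$evalBatchSize, seeds[4], "L-VNC-vs-TNC",
                     cfg$keepPartialBatch),
      batchedMetrics(evalSets$svnc, evalSets$tnc, evalSets$mask,
                     cfg$evalBatchSize, seeds[4], "S-VNC-vs-TNC",
                     cfg$keepPartialBatch))
  })
  summary <- .summarizeBatches(records)
  report <- list(records = records, summary = summary,
                 history = trained$history,
                 valPlateau = min(trained$history@valLoss),
                 manifest = ds$manifest, lookup = lut,
                 model = trained$model)
  if (!is.null(cfg$outDir)) {
    .stage("report", {
      if (!dir.exists(cfg$outDir))
        dir.create(cfg$outDir, recursive = TRUE)
      write.csv(records, file.path(cfg$outDir, "report.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(summary = summary, val_plateau_hu = report$valPlateau),
        file.path(cfg$outDir, "summary.json"), auto_unbox = TRUE,
        digits = NA, dataframe = "rows")
    })
  }
  report
}
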