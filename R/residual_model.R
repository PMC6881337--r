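# Dilated residual network predicting the TNC - L-VNC difference from the
# (low, high, L-VNC) channel triple. The network, its backpropagation and
# the Adam optimizer are implemented here on top of the package's compiled
# im2col convolution kernels; batches are (size, size, channels, N) arrays.

#' Residual-network configuration
#'
#' The "clinical" profile mirrors the clinical-scale settings: 3 groups of 3
#' residual blocks with dilations 1/2/4, 64 channels, 256 x 256 inputs,
#' batch size 8, Adam at a constant 1e-5 with L2 penalty 0.02 and dropout
#' 0.5. The "desk" profile is the CPU-scale variant used throughout the
#' package's synthetic experiments: 8 channels, 64 x 64 inputs, learning
#' rate 1e-3, dropout 0.2 (see the methods vignette for the rationale).
#'
#' @param profile "desk" or "clinical".
#' @param groups,blocksPerGroup,dilations,channels,kernel architecture.
#' @param dropoutRate,weightDecay,learningRate,batchSize,inputSize training
#'   settings.
#' @param normalization "batch" (default) or "none".
#' @return a \linkS4class{NetworkConfig}.
#' @export
networkConfig <- function(profile = c("desk", "clinical"), groups = 3L,
                          blocksPerGroup = 3L, dilations = c(1L, 2L, 4L),
                          channels = NULL, kernel = 3L, dropoutRate = NULL,
                          weightDecay = 0.02, learningRate = NULL,
                          batchSize = 8L, inputSize = NULL,
                          normalization = "batch") {
  profile <- match.arg(profile)
  if (profile == "clinical") {
    if (is.null(channels)) channels <- 64L
    if (is.null(inputSize)) inputSize <- 256L
    if (is.null(learningRate)) learningRate <- 1e-5
    if (is.null(dropoutRate)) dropoutRate <- 0.5
  } else {
    if (is.null(channels)) channels <- 8L
    if (is.null(inputSize)) inputSize <- 64L
    if (is.null(learningRate)) learningRate <- 1e-3
    if (is.null(dropoutRate)) dropoutRate <- 0.2
  }
  new("NetworkConfig", groups = as.integer(groups),
      blocksPerGroup = as.integer(blocksPerGroup),
      dilations = as.integer(dilations), channels = as.integer(channels),
      kernel = as.integer(kernel), dropoutRate = dropoutRate,
      weightDecay = weightDecay, learningRate = learningRate,
      batchSize = as.integer(batchSize), inputSize = as.integer(inputSize),
      normalization = normalization, profile = profile)
}

# HU window mapped to [0, 1] for the input channels; targets stay in HU.
.HU_WINDOW <- c(-100, 300)

.normalizeChannel <- function(x) {
  (x - .HU_WINDOW[1]) / (.HU_WINDOW[2] - .HU_WINDOW[1])
}

.downsample <- function(x, size) {
  H <- nrow(x); W <- ncol(x)
  if (H == size && W == size) return(x)
  if (H %% size != 0L || W %% size != 0L)
    stop("working size must divide the native dimensions")
  fr <- H %/% size; fc <- W %/% size
  t1 <- rowsum(x, rep(seq_len(size), each = fr)) / fr
  unname(t(rowsum(t(t1), rep(seq_len(size), each = fc)))) / fc
}

#' Build a training sample from one slice
#'
#' Resamples the low, high, L-VNC, TNC images and the mask to size x size
#' (area-average pooling; the mask keeps pixels with > 0.5 coverage),
#' normalizes the three input channels from the HU window [-100, 300] to
#' [0, 1], and forms the target difference TNC - L-VNC in raw HU, so that
#' target + L-VNC reproduces the (resampled) TNC exactly.
#'
#' @param pair a \linkS4class{DECTPair}.
#' @param lvnc the (median-filtered) L-VNC \linkS4class{HUImage}.
#' @param tnc the true non-contrast \linkS4class{HUImage}.
#' @param mask a \linkS4class{BrainMask}.
#' @param size working resolution (must divide the native dimensions).
#' @return a \linkS4class{TrainingSample}.
#' @export
makeTrainingSamples <- function(pair, lvnc, tnc, mask, size) {
  d <- dim(pair@low@pixels)
  if (!identical(dim(lvnc@pixels), d) || !identical(dim(tnc@pixels), d) ||
      !identical(dim(mask@pixels), d))
    stop("shape mismatch between pair, lvnc, tnc and mask")
  size <- as.integer(size)
  lowD <- .downsample(pair@low@pixels, size)
  highD <- .downsample(pair@high@pixels, size)
  lvncD <- .downsample(lvnc@pixels, size)
  tncD <- .downsample(tnc@pixels, size)
  maskD <- .downsample(mask@pixels * 1, size) > 0.5
  if (!any(maskD)) stop("resampled mask is empty")
  input <- array(0, c(size, size, 3))
  input[, , 1] <- .normalizeChannel(lowD)
  input[, , 2] <- .normalizeChannel(highD)
  input[, , 3] <- .normalizeChannel(lvncD)
  new("TrainingSample", input = input, target = tncD - lvncD,
      mask = brainMask(maskD), subjectId = pair@low@subjectId,
      sliceId = pair@low@sliceId)
}

# ---- parameter initialization ----

.blockNames <- function(cfg) {
  sprintf("blk%d", seq_len(cfg@groups * cfg@blocksPerGroup))
}

.blockDilation <- function(cfg, bi) {
  cfg@dilations[ceiling(bi / cfg@blocksPerGroup)]
}

#' Build (initialize) a residual network
#'
#' Architecture: a kernel x kernel projection lifting the 3 input channels
#' to \code{channels}; \code{groups} groups of \code{blocksPerGroup}
#' residual blocks, where block = conv -> norm -> ReLU -> dropout -> conv
#' -> norm added to its input, both convolutions using the group's
#' dilation; and a final 1 x 1 convolution down to one channel. Spatial
#' resolution is preserved throughout. Convolution weights use He-normal
#' initialization, deterministic given \code{seed}.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param seed integer seed.
#' @return a \linkS4class{ResidualNet}.
#' @export
buildNetwork <- function(config, seed = 1L) {
  stopifnot(is(config, "NetworkConfig"))
  k <- config@kernel; C <- config@channels
  bn <- config@normalization == "batch"
  params <- list()
  state <- list()
  withSeed(seed, {
    heConv <- function(cin, cout, kk) {
      fan <- cin * kk * kk
      matrix(rnorm(fan * cout, 0, sqrt(2 / fan)), fan, cout)
    }
    params[["conv_in.wt"]] <- heConv(3L, C, k)
    params[["conv_in.b"]] <- numeric(C)
    for (nm in .blockNames(config)) {
      params[[paste0(nm, ".conv1.wt")]] <- heConv(C, C, k)
      params[[paste0(nm, ".conv1.b")]] <- numeric(C)
      params[[paste0(nm, ".conv2.wt")]] <- heConv(C, C, k)
      params[[paste0(nm, ".conv2.b")]] <- numeric(C)
      if (bn) {
        params[[paste0(nm, ".bn1.gamma")]] <- rep(1, C)
        params[[paste0(nm, ".bn1.beta")]] <- numeric(C)
        params[[paste0(nm, ".bn2.gamma")]] <- rep(1, C)
        params[[paste0(nm, ".bn2.beta")]] <- numeric(C)
        state[[paste0(nm, ".bn1.mean")]] <- numeric(C)
        state[[paste0(nm, ".bn1.var")]] <- rep(1, C)
        state[[paste0(nm, ".bn2.mean")]] <- numeric(C)
        state[[paste0(nm, ".bn2.var")]] <- rep(1, C)
      }
    }
    params[["conv_out.wt"]] <- heConv(C, 1L, 1L)
    params[["conv_out.b"]] <- numeric(1)
  })
  new("ResidualNet", config = config, params = params, state = state,
      seed = as.integer(seed))
}

# ---- channel-wise helpers on [S, S, C, N] arrays ----

.chanSums <- function(x, C, N) {
  cs <- .colSums(x, m = length(x) / (C * N), n = C * N)
  .rowSums(matrix(cs, C, N), C, N)
}

.chanExpand <- function(v, P, N) rep(rep(v, each = P), times = N)

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.bnForward <- function(x, gamma, beta, runMean, runVar, training) {
  d <- dim(x); P <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- P * N
  if (training) {
    mu <- .chanSums(x, C, N) / m
    s2 <- .chanSums(x * x, C, N) / m
    va <- pmax(s2 - mu^2, 0)
    newMean <- (1 - .BN_MOMENTUM) * runMean + .BN_MOMENTUM * mu
    newVar <- (1 - .BN_MOMENTUM) * runVar + .BN_MOMENTUM * va
  } else {
    mu <- runMean; va <- runVar
    newMean <- runMean; newVar <- runVar
  }
  invstd <- 1 / sqrt(va + .BN_EPS)
  xhat <- (x - .chanExpand(mu, P, N)) * .chanExpand(invstd, P, N)
  y <- .chanExpand(gamma, P, N) * xhat + .chanExpand(beta, P, N)
  dim(y) <- d; dim(xhat) <- d
  list(y = y, xhat = xhat, invstd = invstd, mean = newMean, var = newVar)
}

.bnBackward <- function(dy, cache, gamma, training) {
  d <- dim(dy); P <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- P * N
  xhat <- cache$xhat
  dgamma <- .chanSums(dy * xhat, C, N)
  dbeta <- .chanSums(dy, C, N)
  if (training) {
    dxhat <- dy * .chanExpand(gamma, P, N)
    sdx <- .chanSums(dxhat, C, N)
    sdxx <- .chanSums(dxhat * xhat, C, N)
    dx <- .chanExpand(cache$invstd, P, N) *
      (dxhat - .chanExpand(sdx / m, P, N) -
         xhat * .chanExpand(sdxx / m, P, N))
  } else {
    dx <- dy * .chanExpand(gamma * cache$invstd, P, N)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward / backward over the whole network ----

.netForward <- function(params, state, cfg, x, training = FALSE,
                        keepCache = FALSE) {
  k <- cfg@kernel
  bn <- cfg@normalization == "batch"
  drop <- training && cfg@dropoutRate > 0
  cache <- if (keepCache) list() else NULL
  a <- .nn_conv_fwd(x, params[["conv_in.wt"]], params[["conv_in.b"]], k, 1L)
  if (keepCache) cache$x <- x
  for (nm in .blockNames(cfg)) {
    bi <- as.integer(sub("blk", "", nm))
    dil <- .blockDilation(cfg, bi)
    aIn <- a
    h1 <- .nn_conv_fwd(aIn, params[[paste0(nm, ".conv1.wt")]],
                       params[[paste0(nm, ".conv1.b")]], k, dil)
    if (bn) {
      c1 <- .bnForward(h1, params[[paste0(nm, ".bn1.gamma")]],
                       params[[paste0(nm, ".bn1.beta")]],
                       state[[paste0(nm, ".bn1.mean")]],
                       state[[paste0(nm, ".bn1.var")]], training)
      o1 <- c1$y
      if (training) {
        state[[paste0(nm, ".bn1.mean")]] <- c1$mean
        state[[paste0(nm, ".bn1.var")]] <- c1$var
      }
    } else { c1 <- NULL; o1 <- h1 }
    reluMask <- o1 > 0
    r1 <- o1 * reluMask
    if (drop) {
      dm <- (runif(length(r1)) >= cfg@dropoutRate) /
        (1 - cfg@dropoutRate)
      dim(dm) <- dim(r1)
      d1 <- r1 * dm
    } else { dm <- NULL; d1 <- r1 }
    h2 <- .nn_conv_fwd(d1, params[[paste0(nm, ".conv2.wt")]],
                       params[[paste0(nm, ".conv2.b")]], k, dil)
    if (bn) {
      c2 <- .bnForward(h2, params[[paste0(nm, ".bn2.gamma")]],
                       params[[paste0(nm, ".bn2.beta")]],
                       state[[paste0(nm, ".bn2.mean")]],
                       state[[paste0(nm, ".bn2.var")]], training)
      o2 <- c2$y
      if (training) {
        state[[paste0(nm, ".bn2.mean")]] <- c2$mean
        state[[paste0(nm, ".bn2.var")]] <- c2$var
      }
    } else { c2 <- NULL; o2 <- h2 }
    a <- aIn + o2
    if (keepCache)
      cache[[nm]] <- list(aIn = aIn, bn1 = c1, reluMask = reluMask,
                          dropMask = dm, d1 = d1, bn2 = c2, dil = dil)
  }
  y <- .nn_conv_fwd(a, params[["conv_out.wt"]], params[["conv_out.b"]],
                    1L, 1L)
  if (keepCache) cache$aLast <- a
  list(y = y, cache = cache, state = state)
}

.netBackward <- function(params, cfg, fwd, dy) {
  k <- cfg@kernel
  bn <- cfg@normalization == "batch"
  cache <- fwd$cache
  grads <- list()
  g <- .nn_conv_bwd(cache$aLast, params[["conv_out.wt"]], dy, 1L, 1L)
  grads[["conv_out.wt"]] <- g$dwt
  grads[["conv_out.b"]] <- g$db
  da <- g$dx
  for (nm in rev(.blockNames(cfg))) {
    cb <- cache[[nm]]
    dres <- da
    dO2 <- da
    if (bn) {
      b2 <- .bnBackward(dO2, cb$bn2, params[[paste0(nm, ".bn2.gamma")]],
                        TRUE)
      grads[[paste0(nm, ".bn2.gamma")]] <- b2$dgamma
      grads[[paste0(nm, ".bn2.beta")]] <- b2$dbeta
      dh2 <- b2$dx
    } else dh2 <- dO2
    g2 <- .nn_conv_bwd(cb$d1, params[[paste0(nm, ".conv2.wt")]], dh2, k,
                       cb$dil)
    grads[[paste0(nm, ".conv2.wt")]] <- g2$dwt
    grads[[paste0(nm, ".conv2.b")]] <- g2$db
    dd1 <- g2$dx
    dr1 <- if (is.null(cb$dropMask)) dd1 else dd1 * cb$dropMask
    dO1 <- dr1 * cb$reluMask
    if (bn) {
      b1 <- .bnBackward(dO1, cb$bn1, params[[paste0(nm, ".bn1.gamma")]],
                        TRUE)
      grads[[paste0(nm, ".bn1.gamma")]] <- b1$dgamma
      grads[[paste0(nm, ".bn1.beta")]] <- b1$dbeta
      dh1 <- b1$dx
    } else dh1 <- dO1
    g1 <- .nn_conv_bwd(cb$aIn, params[[paste0(nm, ".conv1.wt")]], dh1, k,
                       cb$dil)
    grads[[paste0(nm, ".conv1.wt")]] <- g1$dwt
    grads[[paste0(nm, ".conv1.b")]] <- g1$db
    da <- dres + g1$dx
  }
  g0 <- .nn_conv_bwd(cache$x, params[["conv_in.wt"]], da, k, 1L)
  grads[["conv_in.wt"]] <- g0$dwt
  grads[["conv_in.b"]] <- g0$db
  grads
}

# Masked RMSE loss over the pooled masked pixels of a batch.
# Returns the loss and its gradient wrt the prediction.
.maskedRMSELoss <- function(pred, target, maskNum) {
  n <- sum(maskNum)
  if (n == 0) stop("empty mask in loss computation")
  diff <- (pred - target) * maskNum
  mse <- sum(diff * diff) / n
  rmse <- sqrt(mse)
  dpred <- if (rmse > 0) diff / (n * rmse) else diff * 0
  list(loss = rmse, dpred = dpred)
}

.stackSamples <- function(samples, size) {
  N <- length(samples)
  X <- array(0, c(size, size, 3, N))
  Tg <- array(0, c(size, size, 1, N))
  M <- array(0, c(size, size, 1, N))
  for (i in seq_len(N)) {
    X[, , , i] <- samples[[i]]@input
    Tg[, , 1, i] <- samples[[i]]@target
    M[, , 1, i] <- samples[[i]]@mask@pixels * 1
  }
  list(X = X, T = Tg, M = M)
}

.evalLoss <- function(params, state, cfg, stack, batchSize) {
  N <- dim(stack$X)[4]
  ss <- 0; nn <- 0
  for (b in split(seq_len(N), ceiling(seq_len(N) / batchSize))) {
    fwd <- .netForward(params, state, cfg,
                       stack$X[, , , b, drop = FALSE], training = FALSE)
    diff <- (fwd$y - stack$T[, , , b, drop = FALSE]) *
      stack$M[, , , b, drop = FALSE]
    ss <- ss + sum(diff * diff)
    nn <- nn + sum(stack$M[, , , b, drop = FALSE])
  }
  sqrt(ss / nn)
}

#' Train the residual network
#'
#' Minimizes the masked RMSE between the predicted and target difference
#' images over the pooled brain-mask pixels of each batch, plus an L2
#' penalty on the convolution weights, with Adam at the configuration's
#' constant learning rate. Training stops when the validation loss has
#' failed to improve by more than \code{tol} HU for \code{patience} epochs
#' ("plateau"), or at \code{maxEpochs}; the weights of the best validation
#' epoch are returned. Fully deterministic given \code{seed} (data order,
#' dropout and initialization all derive from it).
#'
#' @param model a \linkS4class{ResidualNet} from \code{\link{buildNetwork}}.
#' @param train,val non-empty lists of \linkS4class{TrainingSample}.
#' @param patience epochs without improvement before stopping (default 5).
#' @param maxEpochs epoch cap (default 30).
#' @param seed integer seed.
#' @param tol minimum improvement counted, in HU (default 0.01).
#' @param verbose print per-epoch losses.
#' @return list with \code{model} (best weights) and \code{history}
#'   (\linkS4class{TrainingHistory}).
#' @export
trainModel <- function(model, train, val, patience = 5L, maxEpochs = 30L,
                       seed = 1L, tol = 0.01, verbose = FALSE) {
  stopifnot(is(model, "ResidualNet"))
  if (length(train) == 0L || length(val) == 0L)
    stop("train and val must be non-empty")
  if (patience < 1L) stop("patience must be >= 1")
  cfg <- model@config
  size <- cfg@inputSize
  trS <- .stackSamples(train, size)
  vaS <- .stackSamples(val, size)
  params <- model@params
  state <- model@state
  adamM <- lapply(params, function(p) p * 0)
  adamV <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg@learningRate; wd <- cfg@weightDecay
  tstep <- 0
  Ntr <- dim(trS$X)[4]
  trainLoss <- valLoss <- numeric(0)
  bestVal <- Inf; bestParams <- params; bestState <- state
  bestEpoch <- 0L; badEpochs <- 0L
  stopReason <- "max_epochs"
  withSeed(seed, {
    for (epoch in seq_len(maxEpochs)) {
      perm <- sample.int(Ntr)
      ss <- 0; nn <- 0
      for (b in split(perm, ceiling(seq_along(perm) / cfg@batchSize))) {
        fwd <- .netForward(params, state, cfg,
                           trS$X[, , , b, drop = FALSE], training = TRUE,
                           keepCache = TRUE)
        state <- fwd$state
        loss <- .maskedRMSELoss(fwd$y, trS$T[, , , b, drop = FALSE],
                                trS$M[, , , b, drop = FALSE])
        if (!is.finite(loss$loss))
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        ss <- ss + loss$loss^2 * sum(trS$M[, , , b, drop = FALSE])
        nn <- nn + sum(trS$M[, , , b, drop = FALSE])
        grads <- .netBackward(params, cfg, fwd, loss$dpred)
        tstep <- tstep + 1
        corr1 <- 1 - b1^tstep; corr2 <- 1 - b2^tstep
        for (nm in names(params)) {
          g <- grads[[nm]]
          if (endsWith(nm, ".wt") && wd > 0) g <- g + 2 * wd * params[[nm]]
          adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g
          adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g * g
          params[[nm]] <- params[[nm]] -
            lr * (adamM[[nm]] / corr1) / (sqrt(adamV[[nm]] / corr2) + eps)
        }
      }
      trainLoss <- c(trainLoss, sqrt(ss / nn))
      vl <- .evalLoss(params, state, cfg, vaS, cfg@batchSize)
      if (!is.finite(vl))
        stop(sprintf("non-finite validation loss at epoch %d", epoch))
      valLoss <- c(valLoss, vl)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f HU", epoch,
                        trainLoss[epoch], vl))
      if (vl < bestVal - tol) {
        bestVal <- vl; bestParams <- params; bestState <- state
        bestEpoch <- epoch; badEpochs <- 0L
      } else {
        if (vl < bestVal) {  # still track the best weights
          bestVal <- vl; bestParams <- params; bestState <- state
          bestEpoch <- epoch
        }
        badEpochs <- badEpochs + 1L
        if (badEpochs >= patience) { stopReason <- "plateau"; break }
      }
    }
  })
  model@params <- bestParams
  model@state <- bestState
  history <- new("TrainingHistory", trainLoss = trainLoss,
                 valLoss = valLoss, epochsRun = length(valLoss),
                 bestEpoch = max(bestEpoch, 1L), stopReason = stopReason,
                 seed = as.integer(seed))
  list(model = model, history = history)
}

#' Predict the TNC - L-VNC difference for one sample
#'
#' Runs the network in inference mode (dropout disabled, batch-norm running
#' statistics), returning the predicted difference map in HU at the working
#' resolution.
#'
#' @param model a trained \linkS4class{ResidualNet}.
#' @param sample a \linkS4class{TrainingSample}.
#' @return an \linkS4class{HUImage}.
#' @export
predictDifference <- function(model, sample) {
  stopifnot(is(model, "ResidualNet"), is(sample, "TrainingSample"))
  cfg <- model@config
  d <- dim(sample@input)
  if (d[1] != cfg@inputSize || d[2] != cfg@inputSize)
    stop("sample resolution does not match the model's input size")
  x <- array(sample@input, c(d[1], d[2], 3, 1))
  fwd <- .netForward(model@params, model@state, cfg, x, training = FALSE)
  HUImage(matrix(fwd$y, d[1], d[2]), sliceId = sample@sliceId,
          subjectId = sample@subjectId)
}
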