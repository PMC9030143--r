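# The classifier the package exists for: a per-timepoint residual 1D-CNN
# feature extractor with weights shared across timepoints, fused across the
# (BL, 12m, 24m) sequence by a three-layer LSTM, ending in a linear map and
# sigmoid to one disease probability. Trained by minimizing binary
# cross-entropy with Adam; gradients are exact (manual backpropagation,
# verified against finite differences in the test suite).

#' Training hyperparameters
#'
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param seed RNG seed governing initialization, shuffling, the validation
#'   split and dropout.
#' @param hidden LSTM hidden size per layer.
#' @param featureDim CNN embedding size.
#' @param nLstmLayers number of stacked LSTM layers (3 in the reference
#'   architecture; 0 yields the CNN-only baseline head).
#' @param dropout dropout rate between LSTM layers.
#' @param weightDecay decoupled (AdamW-style) weight-decay coefficient;
#'   regularizes against memorization on small cohorts.
#' @param pretrainEpochs epochs of shared-CNN pretraining with a direct
#'   per-scan head (every timepoint labelled with its subject's label)
#'   before the sequence model is trained; the standard two-stage scheme
#'   for CNN+RNN longitudinal models. Gradients reaching the extractor
#'   through a deep recurrent stack are weak at initialization, so without
#'   this stage the extractor can fail to learn generalizable features on
#'   small cohorts. 0 disables; ignored for cnn-only.
#' @param freezeCnn keep the pretrained extractor fixed while the LSTM and
#'   head train (stage 2 updates recurrent and head parameters only);
#'   protects the generalizable features from being overwritten by
#'   sequence-level memorization on small cohorts.
#' @param valFraction fraction of the training set held out as a
#'   seed-controlled validation split when no explicit validation set is
#'   supplied (used for best-epoch checkpointing).
#' @param cnnBlocks block spec passed to [cnnConfig()].
#' @return Named list of hyperparameters.
#' @export
modelHyper <- function(epochs = 200L, batchSize = 16L, lr = 1e-3, seed = 1L,
                       hidden = 64L, featureDim = 64L, nLstmLayers = 3L,
                       dropout = 0.2, weightDecay = 0, valFraction = 0.2,
                       pretrainEpochs = 30L, freezeCnn = TRUE,
                       cnnBlocks = list(c(16L, 5L, 2L), c(32L, 5L, 2L),
                                        c(64L, 5L, 2L))) {
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       lr = lr, seed = as.integer(seed), hidden = as.integer(hidden),
       featureDim = as.integer(featureDim),
       nLstmLayers = as.integer(nLstmLayers), dropout = dropout,
       weightDecay = weightDecay, valFraction = valFraction,
       pretrainEpochs = as.integer(pretrainEpochs),
       freezeCnn = isTRUE(freezeCnn), cnnBlocks = cnnBlocks)
}

# Map a timepoint scope to the LSTM unroll length (BL -> 1, 12m -> 2,
# 24m / all -> 3): sequences shorter than three steps truncate the unroll.
scopeSteps <- function(scope) {
  switch(scope, BL = 1L, "12m" = 2L, "24m" = 3L, all = 3L,
         stop("config error: unknown scope '", scope, "'"))
}

# Build the design tensor for a sample list: N x L x S array of upper-
# triangle edge vectors plus the label vector. For sequence models S is the
# unroll length (first S timepoints); for single-timepoint models S = 1 and
# `timepointIdx` selects the scan.
buildDesign <- function(samples, steps = 3L, timepointIdx = NULL) {
  n <- length(samples)
  if (n == 0L) stop("input error: no samples")
  L <- roiCount(samples[[1L]]) * (roiCount(samples[[1L]]) - 1L) / 2L
  tps <- if (is.null(timepointIdx)) seq_len(steps) else timepointIdx
  x <- array(0, c(n, L, length(tps)))
  y <- numeric(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    if (length(s@fcList) < max(tps))
      stop("input error: sample ", s@subjectId, " lacks required timepoints")
    for (j in seq_along(tps)) x[i, , j] <- upperTriVec(s@fcList[[tps[j]]])
    y[i] <- s@label
    ids[i] <- s@subjectId
  }
  list(x = x, y = y, ids = ids, L = as.integer(L))
}

standardizeDesign <- function(x, norm = NULL) {
  d <- dim(x)
  flat <- matrix(aperm(x, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
  if (is.null(norm)) {
    mu <- colMeans(flat)
    sd <- pmax(apply(flat, 2L, stats::sd), 1e-6)
    norm <- list(mu = mu, sd = sd)
  }
  flat <- sweep(sweep(flat, 2L, norm$mu, "-"), 2L, norm$sd, "/")
  list(x = aperm(array(flat, c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L)),
       norm = norm)
}

initModelParams <- function(cnnCfg, hyper, integrator = FALSE) {
  lstm <- list()
  if (hyper$nLstmLayers > 0L) {
    dims <- c(hyper$featureDim, rep(hyper$hidden, hyper$nLstmLayers - 1L))
    lstm <- lapply(seq_len(hyper$nLstmLayers), function(l) {
      p <- lstmInitParams(dims[l], hyper$hidden)
      if (integrator) {
        # recency-dominant start: candidate gate passes its input through
        # coordinate-wise, forget gate biased closed and input/output
        # gates open, so the initialized stack approximately forwards the
        # latest scan's features to the head (the pretrained per-scan
        # read-out) and training then learns how much history to keep
        p$Wc[] <- p$Wc * 0.1
        for (i in seq_len(min(dims[l], hyper$hidden)))
          p$Wc[hyper$hidden + i, i] <- 1
        p$bf[] <- -2
        p$bi[] <- 2
        p$bo[] <- 1
      }
      p
    })
  }
  headIn <- if (hyper$nLstmLayers > 0L) hyper$hidden else hyper$featureDim
  list(cnn = cnnInitParams(cnnCfg), lstm = lstm,
       head = list(W = xavierInit(headIn, 1L), b = numeric(1L)))
}

# Forward pass on a batch tensor Xb (B x L x S). Returns probabilities and,
# with cache = TRUE, everything the backward pass needs.
modelForward <- function(Xb, params, cnnCfg, masks = NULL, cache = FALSE) {
  d <- dim(Xb)
  B <- d[1L]; S <- d[3L]
  xBig <- do.call(rbind, lapply(seq_len(S), function(t)
    matrix(Xb[, , t], nrow = B)))
  cf <- cnnForwardBatch(xBig, cnnCfg, params$cnn, cache = cache)
  feats <- lapply(seq_len(S), function(t)
    cf$features[(t - 1L) * B + seq_len(B), , drop = FALSE])
  hasLstm <- length(params$lstm) > 0L
  if (hasLstm) {
    sf <- lstmStackForward(feats, params$lstm, masks)
    headIn <- sf$hTop
  } else {
    sf <- NULL
    headIn <- feats[[1L]]
  }
  hd <- denseForward(headIn, params$head$W, params$head$b)
  prob <- sigmoidFn(drop(hd$out))
  res <- list(prob = prob)
  if (cache)
    res$cache <- list(cnn = cf$cache, stack = sf, head = hd, B = B, S = S)
  res
}

modelBackward <- function(prob, y, fwdCache, params, cnnCfg, masks = NULL) {
  B <- fwdCache$B; S <- fwdCache$S
  dLogit <- matrix((prob - y) / B, ncol = 1L)
  hb <- denseBackward(dLogit, fwdCache$head, params$head$W)
  hasLstm <- length(params$lstm) > 0L
  if (hasLstm) {
    sb <- lstmStackBackward(hb$dx, fwdCache$stack, params$lstm, masks)
    dFeats <- sb$dFeats
    lstmGrads <- sb$grads
  } else {
    dFeats <- list(hb$dx)
    lstmGrads <- list()
  }
  dF <- do.call(rbind, dFeats)
  cb <- cnnBackwardBatch(dF, cnnCfg, params$cnn, fwdCache$cnn)
  list(cnn = cb$grads, lstm = lstmGrads,
       head = list(W = hb$dW, b = hb$db))
}

bceLoss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the longitudinal CNN+LSTM classifier (or a CNN-only baseline)
#'
#' Minimizes binary cross-entropy with Adam over minibatches, recording the
#' training- and validation-loss curve per epoch and returning the
#' parameters of the epoch with the best validation loss. The CNN extractor
#' is a single parameter object applied to every timepoint (weight sharing
#' across the sequence). The run is a deterministic function of the data
#' and `hyper$seed`.
#'
#' @param samples list of [LongitudinalSample-class] training samples
#'   containing both classes.
#' @param valSamples optional explicit validation samples; if NULL, a
#'   seed-controlled fraction `hyper$valFraction` of `samples` is held out.
#' @param method `"cnn-lstm"` (sequence model) or `"cnn-only"`
#'   (single-timepoint baseline, no recurrence).
#' @param scope timepoint scope: for `"cnn-lstm"`, `"BL"`/`"12m"` truncate
#'   the LSTM unroll to 1/2 steps and `"24m"`/`"all"` use the full
#'   three-step sequence; for `"cnn-only"` it names the single scan used
#'   (`"all"` is not meaningful there and is an error).
#' @param hyper hyperparameters from [modelHyper()].
#' @return An object of class `fcModel`: parameters, configs,
#'   standardization statistics, loss curves (`data.frame` epoch/train/val)
#'   and the checkpointed best epoch.
#' @seealso [predictProb()], [classify()]
#' @export
trainModel <- function(samples, valSamples = NULL,
                       method = c("cnn-lstm", "cnn-only"), scope = "all",
                       hyper = modelHyper()) {
  method <- match.arg(method)
  labs <- vapply(samples, function(s) s@label, integer(1))
  if (length(unique(labs)) < 2L)
    stop("input error: training set contains a single class")
  set.seed(hyper$seed)
  if (method == "cnn-only") {
    if (scope == "all")
      stop("config error: cnn-only needs a single timepoint scope")
    tpIdx <- match(scope, timepointLevels())
    steps <- 1L
    hyper$nLstmLayers <- 0L
  } else {
    tpIdx <- NULL
    steps <- scopeSteps(scope)
  }
  if (is.null(valSamples) && hyper$valFraction > 0) {
    nVal <- max(1L, round(hyper$valFraction * length(samples)))
    vi <- sample.int(length(samples), nVal)
    valSamples <- samples[vi]
    samples <- samples[-vi]
    labs <- labs[-vi]
    if (length(unique(labs)) < 2L)
      stop("input error: validation split left a single class in training")
  }
  des <- buildDesign(samples, steps = steps, timepointIdx = tpIdx)
  std <- standardizeDesign(des$x)
  X <- std$x
  y <- des$y
  valDes <- NULL
  if (!is.null(valSamples) && length(valSamples) > 0L) {
    vd <- buildDesign(valSamples, steps = steps, timepointIdx = tpIdx)
    valDes <- list(x = standardizeDesign(vd$x, std$norm)$x, y = vd$y)
  }
  cnnCfg <- cnnConfig(des$L, blocks = hyper$cnnBlocks,
                      featureDim = hyper$featureDim)
  n <- length(y)
  pre <- if (is.null(hyper$pretrainEpochs)) 0L else hyper$pretrainEpochs
  params <- initModelParams(cnnCfg, hyper,
                            integrator = method == "cnn-lstm" && pre > 0L)
  if (method == "cnn-lstm" && pre > 0L) {
    # stage 1: pretrain the shared extractor with a direct per-scan head,
    # every timepoint carrying its subject's label, so the CNN learns
    # discriminative features before they must pass through the stack
    preParams <- list(cnn = params$cnn,
                      head = list(W = xavierInit(hyper$featureDim, 1L),
                                  b = numeric(1L)))
    preOpt <- adamInit(preParams)
    nAll <- n * steps
    Xflat <- array(0, c(nAll, des$L, 1L))
    for (t in seq_len(steps))
      Xflat[(t - 1L) * n + seq_len(n), , 1L] <- X[, , t]
    yFlat <- rep(y, times = steps)
    for (ep in seq_len(pre)) {
      ord <- sample.int(nAll)
      for (bi in seq_len(ceiling(nAll / hyper$batchSize))) {
        idx <- ord[((bi - 1L) * hyper$batchSize + 1L):
                     min(bi * hyper$batchSize, nAll)]
        fw <- modelForward(Xflat[idx, , , drop = FALSE],
                           list(cnn = preParams$cnn, lstm = list(),
                                head = preParams$head), cnnCfg,
                           cache = TRUE)
        gb <- modelBackward(fw$prob, yFlat[idx], fw$cache,
                            list(cnn = preParams$cnn, lstm = list(),
                                 head = preParams$head), cnnCfg)
        st <- adamStep(preParams, list(cnn = gb$cnn, head = gb$head),
                       preOpt, lr = hyper$lr)
        preParams <- st$params
        preOpt <- st$state
      }
    }
    params$cnn <- preParams$cnn
    # with the integrator start the top hidden state tracks the integrated
    # features coordinate-wise, so the pretrained per-scan head is a
    # sensible first read-out (Adam rescales it within a few steps)
    if (hyper$hidden == hyper$featureDim)
      params$head$W <- preParams$head$W
  }
  frozen <- method == "cnn-lstm" && pre > 0L && isTRUE(hyper$freezeCnn)
  opt <- adamInit(params)
  nBatch <- ceiling(n / hyper$batchSize)
  useDrop <- method == "cnn-lstm" && hyper$dropout > 0 &&
    hyper$nLstmLayers > 1L
  trainLoss <- valLoss <- rep(NA_real_, hyper$epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    batchLosses <- numeric(nBatch)
    for (bi in seq_len(nBatch)) {
      idx <- ord[((bi - 1L) * hyper$batchSize + 1L):min(bi * hyper$batchSize, n)]
      Xb <- X[idx, , , drop = FALSE]
      yb <- y[idx]
      masks <- NULL
      if (useDrop) {
        masks <- lapply(seq_len(hyper$nLstmLayers - 1L), function(l)
          matrix(stats::rbinom(length(idx) * hyper$hidden, 1L,
                               1 - hyper$dropout) / (1 - hyper$dropout),
                 length(idx), hyper$hidden))
      }
      fw <- modelForward(Xb, params, cnnCfg, masks = masks, cache = TRUE)
      batchLosses[bi] <- bceLoss(fw$prob, yb)
      if (!is.finite(batchLosses[bi]))
        stop("training-divergence error: non-finite loss at epoch ", ep)
      grads <- modelBackward(fw$prob, yb, fw$cache, params, cnnCfg,
                             masks = masks)
      if (frozen) grads$cnn <- treeZero(grads$cnn)
      st <- adamStep(params, grads, opt, lr = hyper$lr,
                     weightDecay = if (is.null(hyper$weightDecay)) 0
                                   else hyper$weightDecay)
      params <- st$params
      opt <- st$state
    }
    trainLoss[ep] <- mean(batchLosses)
    monitor <- trainLoss[ep]
    if (!is.null(valDes)) {
      vp <- modelForward(valDes$x, params, cnnCfg)$prob
      valLoss[ep] <- bceLoss(vp, valDes$y)
      monitor <- valLoss[ep]
    }
    if (monitor < best$loss)
      best <- list(loss = monitor, params = params, epoch = ep)
  }
  structure(list(params = best$params, finalParams = params,
                 cnnCfg = cnnCfg, method = method, scope = scope,
                 steps = steps, timepointIdx = tpIdx, norm = std$norm,
                 lossCurves = data.frame(epoch = seq_len(hyper$epochs),
                                         train = trainLoss, val = valLoss),
                 bestEpoch = best$epoch, hyper = hyper),
            class = "fcModel")
}

#' Predict disease probabilities for longitudinal samples
#'
#' Runs the trained model in inference mode (no dropout); deterministic.
#'
#' @param model an `fcModel` from [trainModel()].
#' @param samples list of [LongitudinalSample-class] objects.
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
predictProb <- function(model, samples) {
  des <- buildDesign(samples, steps = model$steps,
                     timepointIdx = model$timepointIdx)
  X <- standardizeDesign(des$x, model$norm)$x
  p <- modelForward(X, model$params, model$cnnCfg)$prob
  names(p) <- des$ids
  p
}

#' Classify one longitudinal sample
#'
#' The three FC matrices pass through the shared-weight CNN, the embedding
#' sequence through the LSTM stack, and the final top-layer hidden state
#' through the sigmoid head; the decision threshold is 0.5.
#'
#' @param sample a [LongitudinalSample-class].
#' @param model an `fcModel` from [trainModel()].
#' @return List with `prob` (probability of the positive, more-diseased
#'   class) and `label` (0/1 decision at threshold 0.5).
#' @export
classify <- function(sample, model) {
  if (!is(sample, "LongitudinalSample"))
    stop("input error: sample must be a LongitudinalSample")
  p <- unname(predictProb(model, list(sample)))
  list(prob = p, label = as.integer(p >= 0.5))
}

#' @export
print.fcModel <- function(x, ...) {
  cat(sprintf(
    "fcModel (%s, scope %s): %d-step unroll, featureDim %d, hidden %d x %d layers\n  best epoch %d of %d (monitored loss %.4f)\n",
    x$method, x$scope, x$steps, x$hyper$featureDim, x$hyper$hidden,
    x$hyper$nLstmLayers, x$bestEpoch, x$hyper$epochs,
    min(c(x$lossCurves$val, x$lossCurves$train), na.rm = TRUE)))
  invisible(x)
}

#' Serialize / restore a trained model
#'
#' The weights go to one binary file and the architecture (configs, scope,
#' standardization statistics) to a JSON descriptor alongside it.
#'
#' @param model an `fcModel`.
#' @param path base path; `.rds` and `.json` suffixes are appended.
#' @return `saveModel` returns the base path invisibly; `loadModel` the
#'   restored model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  meta <- list(method = model$method, scope = model$scope,
               steps = model$steps, bestEpoch = model$bestEpoch,
               hyper = model$hyper[c("epochs", "batchSize", "lr", "seed",
                                     "hidden", "featureDim", "nLstmLayers",
                                     "dropout")],
               inputLength = model$cnnCfg$inputLength)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(paste0(path, ".rds"))
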