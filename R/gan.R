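# GAN augmentation of functional-connectivity matrices: a small
# generator/discriminator pair trained adversarially on the vectorized
# upper triangle of same-class FC matrices, with post-hoc projection
# guaranteeing every generated sample is a valid correlation matrix.

#' GAN configuration
#'
#' @param noiseDim latent noise dimension.
#' @param genWidths hidden-layer widths of the generator MLP.
#' @param discWidths hidden-layer widths of the discriminator MLP.
#' @param epochs adversarial training epochs.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate (both networks).
#' @param perClass train one conditional generator per class label.
#' @param seed RNG seed.
#' @return Named config list.
#' @export
ganConfig <- function(noiseDim = 32L, genWidths = c(64L), discWidths = c(64L),
                      epochs = 200L, batchSize = 16L, lr = 1e-3,
                      perClass = TRUE, seed = 1L) {
  stopifnot(noiseDim >= 1L, all(genWidths >= 1L), all(discWidths >= 1L),
            epochs >= 1L, batchSize >= 1L)
  list(noiseDim = as.integer(noiseDim), genWidths = as.integer(genWidths),
       discWidths = as.integer(discWidths), epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), lr = lr, perClass = perClass,
       seed = as.integer(seed))
}

# -- small MLP with ReLU hidden layers and a configurable output map -------

mlpInit <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = heInit(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L]))
  })
}

# outAct: "tanh" (generator), "linear" (discriminator logit)
mlpForward <- function(x, layers, outAct = "linear") {
  nL <- length(layers)
  caches <- vector("list", nL)
  for (i in seq_len(nL)) {
    dn <- denseForward(x, layers[[i]]$W, layers[[i]]$b)
    if (i < nL) {
      rl <- reluForward(dn$out)
      caches[[i]] <- list(dense = dn, relu = rl)
      x <- rl$out
    } else {
      out <- if (outAct == "tanh") tanh(dn$out) else dn$out
      caches[[i]] <- list(dense = dn, out = out)
      x <- out
    }
  }
  list(out = x, caches = caches)
}

mlpBackward <- function(dout, fwd, layers, outAct = "linear") {
  nL <- length(layers)
  grads <- vector("list", nL)
  for (i in rev(seq_len(nL))) {
    ca <- fwd$caches[[i]]
    if (i == nL && outAct == "tanh")
      dout <- dout * (1 - ca$out * ca$out)
    if (i < nL) dout <- reluBackward(dout, ca$relu)
    db <- denseBackward(dout, ca$dense, layers[[i]]$W)
    grads[[i]] <- list(W = db$dW, b = db$db)
    dout <- db$dx
  }
  list(grads = grads, dx = dout)
}

#' Project an arbitrary square matrix to a valid FC matrix
#'
#' Symmetrizes via (M + t(M))/2, clips entries to \[-1, 1\], and sets the
#' diagonal to 1. Idempotent; positive semi-definiteness is deliberately
#' not enforced (the classifier consumes raw matrices and no downstream
#' step requires it).
#'
#' @param raw square numeric matrix with finite entries.
#' @param subjectId,timepoint identity for the resulting object.
#' @return An [FCMatrix-class].
#' @export
#' @examples
#' m <- matrix(c(0.9, 1.3, 1.1, 0.9), 2, 2)
#' fcValues(projectToValidFC(m))
projectToValidFC <- function(raw, subjectId = "projected", timepoint = "BL") {
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("input error: non-finite entries")
  if (nrow(raw) != ncol(raw)) stop("input error: matrix must be square")
  m <- (raw + t(raw)) / 2
  m <- pmin(pmax(m, -1), 1)
  diag(m) <- 1
  fcMatrix(m, subjectId = subjectId, timepoint = timepoint)
}

#' Train a GAN on same-class FC matrices
#'
#' Standard minimax adversarial training with the non-saturating generator
#' loss, on the vectorized strict upper triangle (length R(R-1)/2) of the
#' supplied matrices. The generator maps gaussian noise through a ReLU MLP
#' with a tanh output (edge correlations live in \[-1, 1\]); the
#' discriminator is a ReLU MLP with a sigmoid head. Deterministic given the
#' config seed and the sample order.
#'
#' @param realSamples list of [FCMatrix-class] objects sharing one class
#'   label, all with the same ROI count (at least 2 samples).
#' @param config a [ganConfig()].
#' @param classLabel label recorded on the generator state.
#' @return A `fcGenerator` object: generator parameters, config, ROI count,
#'   class label, and a per-epoch history (discriminator/generator loss and
#'   mean entrywise distance of the epoch's fakes to the real mean).
#' @export
trainGAN <- function(realSamples, config = ganConfig(), classLabel = "0") {
  if (length(realSamples) < 2L)
    stop("input error: at least 2 real samples are required")
  R <- roiCount(realSamples[[1L]])
  if (!all(vapply(realSamples, roiCount, integer(1)) == R))
    stop("input error: all samples must share one ROI count")
  X <- t(vapply(realSamples, upperTriVec, numeric(R * (R - 1L) / 2L)))
  L <- ncol(X)
  set.seed(config$seed)
  gen <- mlpInit(c(config$noiseDim, config$genWidths, L))
  disc <- mlpInit(c(L, config$discWidths, 1L))
  optG <- adamInit(gen)
  optD <- adamInit(disc)
  n <- nrow(X)
  bs <- min(config$batchSize, n)
  nBatch <- ceiling(n / bs)
  realMean <- colMeans(X)
  hist <- data.frame(epoch = seq_len(config$epochs), dLoss = NA_real_,
                     gLoss = NA_real_, meanDist = NA_real_)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    dls <- gls <- mds <- numeric(nBatch)
    for (bi in seq_len(nBatch)) {
      idx <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n)]
      xr <- X[idx, , drop = FALSE]
      B <- nrow(xr)
      # --- discriminator step ---
      z <- matrix(stats::rnorm(B * config$noiseDim), B)
      gf <- mlpForward(z, gen, outAct = "tanh")
      xf <- gf$out
      fr <- mlpForward(xr, disc)
      ff <- mlpForward(xf, disc)
      pr <- sigmoidFn(fr$out)
      pf <- sigmoidFn(ff$out)
      dl <- -mean(log(pmax(pr, 1e-12))) - mean(log(pmax(1 - pf, 1e-12)))
      if (!is.finite(dl))
        stop("training-divergence error: non-finite discriminator loss at epoch ",
             ep)
      gr <- mlpBackward((pr - 1) / B, fr, disc)$grads
      gfk <- mlpBackward(pf / B, ff, disc)$grads
      gD <- treeMap2(`+`, gr, gfk)
      sD <- adamStep(disc, gD, optD, lr = config$lr, beta1 = 0.5)
      disc <- sD$params
      optD <- sD$state
      # --- generator step (non-saturating: maximize log D(G(z))) ---
      z <- matrix(stats::rnorm(B * config$noiseDim), B)
      gf <- mlpForward(z, gen, outAct = "tanh")
      ff <- mlpForward(gf$out, disc)
      pf <- sigmoidFn(ff$out)
      gl <- -mean(log(pmax(pf, 1e-12)))
      if (!is.finite(gl))
        stop("training-divergence error: non-finite generator loss at epoch ",
             ep)
      dxFake <- mlpBackward((pf - 1) / B, ff, disc)$dx
      gG <- mlpBackward(dxFake, gf, gen, outAct = "tanh")$grads
      sG <- adamStep(gen, gG, optG, lr = config$lr, beta1 = 0.5)
      gen <- sG$params
      optG <- sG$state
      dls[bi] <- dl
      gls[bi] <- gl
      mds[bi] <- mean(abs(sweep(gf$out, 2L, realMean, "-")))
    }
    hist$dLoss[ep] <- mean(dls)
    hist$gLoss[ep] <- mean(gls)
    hist$meanDist[ep] <- mean(mds)
  }
  structure(list(gen = gen, config = config, roiCount = R,
                 classLabel = as.character(classLabel), history = hist),
            class = "fcGenerator")
}

#' Generate synthetic FC matrices from a trained generator
#'
#' Samples latent noise, maps it through the generator, rebuilds each
#' upper-triangle vector into a full matrix, and projects it to validity
#' with [projectToValidFC()]; every output therefore satisfies all FC
#' matrix invariants.
#'
#' @param generator an `fcGenerator` from [trainGAN()].
#' @param n number of matrices (positive).
#' @param seed RNG seed.
#' @param timepoint timepoint recorded on the outputs.
#' @return List of `n` [FCMatrix-class] objects with subject ids prefixed
#'   `synth-` (provenance tag for leak auditing).
#' @export
generateFC <- function(generator, n, seed = 1L, timepoint = "BL") {
  if (!inherits(generator, "fcGenerator"))
    stop("input error: generator must come from trainGAN()")
  if (n <= 0L) stop("input error: n must be positive")
  set.seed(seed)
  z <- matrix(stats::rnorm(n * generator$config$noiseDim), n)
  v <- mlpForward(z, generator$gen, outAct = "tanh")$out
  lapply(seq_len(n), function(i) {
    projectToValidFC(vecToSymmetric(v[i, ]),
                     subjectId = sprintf("synth-%s-%03d",
                                         generator$classLabel, i),
                     timepoint = timepoint)
  })
}

#' Serialize / restore a trained generator
#'
#' Weights to one binary file, metadata (class label, ROI count, config,
#' seed) to a JSON sidecar.
#'
#' @param generator an `fcGenerator`.
#' @param path base path; `.rds` and `.json` suffixes are appended.
#' @return `saveGenerator` returns the base path invisibly; `loadGenerator`
#'   the restored generator.
#' @export
saveGenerator <- function(generator, path) {
  saveRDS(generator, paste0(path, ".rds"))
  jsonlite::write_json(
    list(classLabel = generator$classLabel, roiCount = generator$roiCount,
         config = generator$config),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveGenerator
#' @export
loadGenerator <- function(path) readRDS(paste0(path, ".rds"))

#' Augment a training set with GAN-generated longitudinal samples
#'
#' Trains one generator per (class, timepoint) cell on the training
#' samples only, draws `ratio` synthetic matrices per real sample of that
#' class, and assembles them into synthetic [LongitudinalSample-class]
#' subjects (the i-th generated BL/12m/24m matrices form subject i).
#' Synthetic subjects carry `synth-` ids so cross-validation can assert
#' that no generated sample ever derives from a test fold.
#'
#' @param samples list of [LongitudinalSample-class] training samples.
#' @param ratio synthetic-to-real ratio (default 1).
#' @param config a [ganConfig()].
#' @return The input list extended with the synthetic samples.
#' @export
augmentSamples <- function(samples, ratio = 1, config = ganConfig()) {
  labs <- vapply(samples, function(s) s@label, integer(1))
  out <- samples
  for (cl in unique(labs)) {
    cls <- samples[labs == cl]
    nSynth <- round(ratio * length(cls))
    if (nSynth < 1L) next
    perTp <- list()
    for (ti in seq_along(timepointLevels())) {
      tp <- timepointLevels()[ti]
      reals <- lapply(cls, function(s) s@fcList[[ti]])
      cfg <- config
      cfg$seed <- deriveSeed(config$seed, paste0("gan-", cl, "-", tp))
      g <- trainGAN(reals, cfg, classLabel = as.character(cl))
      perTp[[tp]] <- generateFC(g, nSynth,
                                seed = deriveSeed(cfg$seed, "draw"),
                                timepoint = tp)
    }
    for (i in seq_len(nSynth)) {
      sid <- sprintf("synth-%s-%03d", cl, i)
      fcs <- lapply(seq_along(timepointLevels()), function(ti) {
        f <- perTp[[ti]][[i]]
        f@subjectId <- sid
        f
      })
      out[[sid]] <- longitudinalSample(fcs, label = cl, subjectId = sid)
    }
  }
  out
}
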