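ns <- asNamespace("LongFC")

test_that("CNN config validates shapes at build time, not run time", {
  cfg <- cnnConfig(190)
  expect_equal(cfg$lengths, c(190L, 95L, 47L, 23L))
  expect_error(cnnConfig(190, shortcuts = list(c(1L, 3L))), "exactly two")
  expect_error(cnnConfig(190, shortcuts = list(c(3L, 1L), c(2L, 4L))),
               "config error")
  expect_error(cnnConfig(190, blocks = list(c(16L, 4L, 2L), c(32L, 5L, 2L)),
                         shortcuts = list(c(1L, 2L), c(1L, 3L))),
               "odd")
  expect_error(cnnConfig(3, blocks = list(c(4L, 3L, 2L), c(4L, 3L, 2L),
                                          c(4L, 3L, 2L))),
               "length 0")
})

test_that("CNN output has the configured dimension and inference is deterministic", {
  set.seed(31)
  fc <- randomFC(10)
  cfg <- cnnConfig(45, blocks = list(c(4L, 3L, 2L), c(6L, 3L, 2L)),
                   shortcuts = list(c(1L, 2L), c(1L, 3L)), featureDim = 7L)
  params <- ns$cnnInitParams(cfg)
  f1 <- cnnForward(fc, cfg, params)
  f2 <- cnnForward(fc, cfg, params)
  expect_length(f1, 7)
  expect_identical(f1, f2)
  expect_error(cnnForward(rnorm(44), cfg, params), "input error")
})

test_that("with zero conv weights the shortcut path carries the signal", {
  set.seed(32)
  cfg <- cnnConfig(45, blocks = list(c(4L, 3L, 2L), c(4L, 3L, 2L)),
                   shortcuts = list(c(1L, 2L), c(1L, 3L)), featureDim = 5L)
  params <- ns$cnnInitParams(cfg)
  # zero the second conv block: its pre-activation input is then exactly the
  # projected shortcut plus block-1 output; zero both to isolate the shortcut
  params$blocks[[2]]$W[] <- 0
  params$blocks[[2]]$b[] <- 0
  x <- matrix(abs(rnorm(45)), 1)
  full <- ns$cnnForwardBatch(x, cfg, params, cache = TRUE)
  # destination input = block1 output + projected source activation
  sc <- ns$shortcutForward(full$cache$blocks[[1]]$pool$out, 1L, cfg,
                           cfg$shortcuts[[1]], params$shortcuts[[1]])
  din <- full$cache$blocks[[1]]$pool$out + sc$out
  # centre tap of the kernel-3 im2col matrix is the raw destination input
  expect_equal(full$cache$blocks[[2]]$conv$M[, 5:8],
               unname(din), ignore_attr = TRUE)
})

test_that("analytic gradients of the composed model match finite differences", {
  set.seed(33)
  L <- 15  # R = 6 regions
  hy <- modelHyper(hidden = 4L, featureDim = 5L, nLstmLayers = 3L,
                   dropout = 0,
                   cnnBlocks = list(c(3L, 3L, 2L), c(4L, 3L, 2L)))
  cfg <- cnnConfig(L, blocks = hy$cnnBlocks,
                   shortcuts = list(c(1L, 2L), c(1L, 3L)),
                   featureDim = hy$featureDim)
  params <- ns$initModelParams(cfg, hy)
  X <- array(rnorm(4 * L * 3), c(4, L, 3))
  y <- c(0, 1, 1, 0)
  fw <- ns$modelForward(X, params, cfg, cache = TRUE)
  grads <- ns$modelBackward(fw$prob, y, fw$cache, params, cfg)
  lossAt <- function(vec) {
    p <- utils::relist(vec, params)
    ns$bceLoss(ns$modelForward(X, p, cfg)$prob, y)
  }
  vec <- unlist(params)
  gvec <- unlist(grads)
  eps <- 1e-4
  idx <- sort(sample.int(length(vec), 80))
  for (k in idx) {
    v1 <- vec; v1[k] <- vec[k] + eps
    v2 <- vec; v2[k] <- vec[k] - eps
    num <- (lossAt(v1) - lossAt(v2)) / (2 * eps)
    # denominator floor keeps the relative comparison meaningful where the
    # true gradient is at finite-difference noise level
    rel <- abs(num - gvec[k]) / max(1e-6, abs(num) + abs(gvec[k]))
    expect_lt(rel, 1e-4)
  }
})

test_that("probabilities are valid and a zero head gives exactly 0.5", {
  ch <- tinyCohort(groups = c(NC = 4, AD = 4), roiCount = 8,
                   framesPerScan = 30)
  s <- cohortSamples(ch, "nc-ad")
  m <- trainModel(s, method = "cnn-lstm", scope = "all",
                  hyper = tinyHyper(epochs = 2, seed = 3))
  p <- predictProb(m, s)
  expect_true(all(p >= 0 & p <= 1))
  m0 <- m
  m0$params$head$W[] <- 0
  m0$params$head$b[] <- 0
  expect_equal(unname(predictProb(m0, s[1])), 0.5)
  cl <- classify(s[[1]], m)
  expect_true(cl$prob >= 0 && cl$prob <= 1)
  expect_true(cl$label %in% c(0L, 1L))
})

test_that("the CNN is one shared parameter object across timepoints", {
  ch <- tinyCohort(groups = c(NC = 4, AD = 4), roiCount = 8,
                   framesPerScan = 30)
  s <- cohortSamples(ch, "nc-ad")
  m <- trainModel(s, method = "cnn-lstm", scope = "all",
                  hyper = tinyHyper(epochs = 2, seed = 4))
  # one parameter set exists; permuting a sample's timepoints changes the
  # output (the sequence model is order-sensitive), while re-running the
  # same input does not
  expect_named(m$params, c("cnn", "lstm", "head"))
  sOrig <- s[[1]]
  sPerm <- sOrig
  sPerm@fcList <- sPerm@fcList[c(3, 2, 1)]
  for (i in 1:3) sPerm@fcList[[i]]@timepoint <- timepointLevels()[i]
  orderSensitive <- FALSE
  for (seed in 1:20) {
    mm <- m
    set.seed(seed)
    mm$params <- ns$treeMap(function(w) w + rnorm(length(w), sd = 0.05),
                            m$params)
    p1 <- unname(predictProb(mm, list(sOrig)))
    p2 <- unname(predictProb(mm, list(sPerm)))
    expect_equal(unname(predictProb(mm, list(sOrig))), p1)
    if (abs(p1 - p2) > 1e-8) orderSensitive <- TRUE
  }
  expect_true(orderSensitive)
})

test_that("training bookkeeping: loss curve length, determinism, class check", {
  ch <- tinyCohort(groups = c(NC = 5, AD = 5), roiCount = 8,
                   framesPerScan = 30)
  s <- cohortSamples(ch, "nc-ad")
  hy <- tinyHyper(epochs = 4, seed = 7)
  m1 <- trainModel(s, method = "cnn-lstm", scope = "all", hyper = hy)
  expect_equal(nrow(m1$lossCurves), 4)
  expect_true(all(is.finite(m1$lossCurves$train)))
  expect_true(all(is.finite(m1$lossCurves$val)))
  m2 <- trainModel(s, method = "cnn-lstm", scope = "all", hyper = hy)
  expect_identical(m1$params, m2$params)
  onlyNC <- s[vapply(s, function(x) x@label, integer(1)) == 0]
  expect_error(trainModel(onlyNC, hyper = hy), "single class")
})

test_that("a separable toy cohort is fit to 100% training accuracy within 50 epochs", {
  ch <- tinyCohort(groups = c(NC = 10, AD = 10), roiCount = 10,
                   framesPerScan = 80, edgeEffect = 0.9, seed = 44,
                   affectedEdgeFraction = 0.5)
  s <- cohortSamples(ch, "nc-ad")
  # pretrained but unfrozen: the full model has the capacity to drive
  # training error to zero on a separable cohort
  hy <- tinyHyper(epochs = 50, seed = 8, valFraction = 0,
                  freezeCnn = FALSE)
  m <- trainModel(s, method = "cnn-lstm", scope = "all", hyper = hy)
  p <- predictProb(m, s)
  labs <- vapply(s, function(x) x@label, integer(1))
  expect_equal(mean((p >= 0.5) == labs[names(p)]), 1)
})

test_that("scope controls the LSTM unroll and cnn-only needs a single timepoint", {
  ch <- tinyCohort(groups = c(NC = 5, AD = 5), roiCount = 8,
                   framesPerScan = 30)
  s <- cohortSamples(ch, "nc-ad")
  mBL <- trainModel(s, method = "cnn-lstm", scope = "BL",
                    hyper = tinyHyper(epochs = 2, seed = 9))
  expect_equal(mBL$steps, 1L)
  m12 <- trainModel(s, method = "cnn-lstm", scope = "12m",
                    hyper = tinyHyper(epochs = 2, seed = 9))
  expect_equal(m12$steps, 2L)
  expect_error(trainModel(s, method = "cnn-only", scope = "all",
                          hyper = tinyHyper(epochs = 2)),
               "config error")
  mc <- trainModel(s, method = "cnn-only", scope = "24m",
                   hyper = tinyHyper(epochs = 2, seed = 9))
  expect_length(mc$params$lstm, 0)
  expect_true(all(predictProb(mc, s) >= 0 & predictProb(mc, s) <= 1))
})

test_that("models round-trip through serialization", {
  ch <- tinyCohort(groups = c(NC = 4, AD = 4), roiCount = 8,
                   framesPerScan = 30)
  s <- cohortSamples(ch, "nc-ad")
  m <- trainModel(s, method = "cnn-lstm", scope = "all",
                  hyper = tinyHyper(epochs = 2, seed = 10))
  dir <- withr::local_tempdir()
  saveModel(m, file.path(dir, "model"))
  back <- loadModel(file.path(dir, "model"))
  expect_identical(predictProb(back, s), predictProb(m, s))
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  expect_equal(meta$method, "cnn-lstm")
})
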