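# Cross-validated evaluation: stratified subject-level 5-fold splitting,
# confusion-matrix metrics, ROC/AUC, and the method-comparison harness
# (linear SVM and CNN-only baselines against the CNN+LSTM sequence model).

#' Stratified subject-level k-fold assignment
#'
#' Partitions subjects into k folds, stratified by class (each fold's class
#' counts within one subject of balance). Splitting is by subject, so all
#' of a subject's timepoints stay in one fold. Deterministic given the
#' seed.
#'
#' @param subjects character vector of subject ids.
#' @param labels 0/1 labels, one per subject.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return Named integer vector mapping subject id to fold index in 0..k-1.
#' @export
#' @examples
#' f <- kfoldSplit(sprintf("s%02d", 1:20), rep(0:1, each = 10), seed = 1)
#' table(f)
kfoldSplit <- function(subjects, labels, k = 5L, seed = 1L) {
  if (length(subjects) != length(labels))
    stop("input error: subjects and labels differ in length")
  if (anyDuplicated(subjects)) stop("input error: duplicate subject ids")
  set.seed(seed)
  fold <- integer(length(subjects))
  names(fold) <- subjects
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("input error: class ", cl, " has fewer subjects (", length(idx),
           ") than folds (", k, ")")
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k) - 1L, length(idx))
  }
  fold
}

#' Confusion-matrix metrics: accuracy, precision, recall
#'
#' accuracy = (TP + TN) / (TP + TN + FN + FP), precision = TP / (TP + FP),
#' recall = TP / (TP + FN), each reported both as a proportion and as a
#' percentage. A metric whose denominator is zero is undefined and
#' reported as NA with a warning, never as 0.
#'
#' @param counts named list or vector with `TP`, `TN`, `FP`, `FN`
#'   (non-negative, total at least 1).
#' @return List with `accuracy`, `precision`, `recall` (proportions),
#'   their `*Pct` percentage forms, and the counts.
#' @export
#' @examples
#' computeMetrics(c(TP = 9, TN = 8, FP = 1, FN = 2))
computeMetrics <- function(counts) {
  counts <- as.list(counts)
  for (f in c("TP", "TN", "FP", "FN"))
    if (is.null(counts[[f]]) || counts[[f]] < 0)
      stop("input error: counts need non-negative TP, TN, FP, FN")
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total < 1) stop("input error: empty confusion table")
  acc <- (TP + TN) / total
  if (TP + FP == 0) {
    warning("precision undefined (TP + FP = 0); reported as NA")
    prec <- NA_real_
  } else prec <- TP / (TP + FP)
  if (TP + FN == 0) {
    warning("recall undefined (TP + FN = 0); reported as NA")
    rec <- NA_real_
  } else rec <- TP / (TP + FN)
  list(accuracy = acc, precision = prec, recall = rec,
       accuracyPct = 100 * acc, precisionPct = 100 * prec,
       recallPct = 100 * rec,
       counts = list(TP = TP, TN = TN, FP = FP, FN = FN))
}

confusionCounts <- function(truth, predicted) {
  list(TP = sum(truth == 1 & predicted == 1),
       TN = sum(truth == 0 & predicted == 0),
       FP = sum(truth == 0 & predicted == 1),
       FN = sum(truth == 1 & predicted == 0))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct scores (ties grouped),
#' accumulating (FPR, TPR) points from (0, 0) to (1, 1), and integrates by
#' the trapezoid rule. Equivalent to the Mann-Whitney U statistic divided
#' by the number of positive-negative pairs, with ties counted half.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels 0/1 truth, both classes present.
#' @return List with `roc` (data.frame of threshold, fpr, tpr) and `auc`.
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc
rocAuc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("input error: scores and labels differ in length")
  if (length(unique(labels)) < 2L)
    stop("input error: both classes must be present")
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr) + 1L)
  for (i in seq_along(thr)) {
    tpr[i + 1L] <- sum(scores >= thr[i] & labels == 1) / nPos
    fpr[i + 1L] <- sum(scores >= thr[i] & labels == 0) / nNeg
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc)
}

# Fit a linear-kernel SVM baseline on single-timepoint edge vectors.
fitSvm <- function(samples, timepointIdx) {
  x <- t(vapply(samples, function(s) upperTriVec(s@fcList[[timepointIdx]]),
                numeric(roiCount(samples[[1L]]) *
                          (roiCount(samples[[1L]]) - 1L) / 2L)))
  y <- factor(vapply(samples, function(s) s@label, integer(1)),
              levels = c(0L, 1L))
  e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
}

predictSvm <- function(fit, samples, timepointIdx) {
  x <- t(vapply(samples, function(s) upperTriVec(s@fcList[[timepointIdx]]),
                numeric(roiCount(samples[[1L]]) *
                          (roiCount(samples[[1L]]) - 1L) / 2L)))
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  # orient the margin so larger means class 1 (e1071 names the column
  # "first/second" with positive values favouring the first level)
  if (startsWith(colnames(dv)[1L], "0/")) -dv[, 1L] else dv[, 1L]
}

#' Cross-validated comparison of classification methods
#'
#' Runs stratified subject-level 5-fold cross-validation of the requested
#' methods on a cohort's task samples, mirroring the comparison design of
#' the longitudinal study: `svm-linear` and `cnn-only` consume a single
#' timepoint's FC matrix; `cnn-lstm` consumes the sequence up to the scope
#' timepoint (BL and 12m scopes truncate the LSTM unroll to 1 and 2 steps).
#' Scope `"all"` evaluates single-timepoint methods at each timepoint
#' separately and the sequence model on the full three-step sequence.
#' Everything (model fitting, augmentation generators, standardization) is
#' fit strictly inside each training fold; pooled (micro) metrics over the
#' five test folds are the headline numbers, with per-fold mean and sd
#' alongside.
#'
#' @param samples list of [LongitudinalSample-class] objects (e.g. from
#'   [cohortSamples()]).
#' @param methods subset of `c("svm-linear", "cnn-only", "cnn-lstm")`.
#' @param scope `"BL"`, `"12m"`, `"24m"`, or `"all"`.
#' @param k folds (default 5).
#' @param seed seed for fold assignment and model training.
#' @param hyper [modelHyper()] for the neural models.
#' @param augmentRatio synthetic-to-real augmentation ratio applied inside
#'   each training fold for the neural models (0 disables augmentation).
#' @param ganCfg [ganConfig()] used when `augmentRatio > 0`.
#' @return List with `table` (data.frame: method, timepoint, pooled
#'   accuracy/precision/recall in %, AUC, per-fold mean and sd of
#'   accuracy), `roc` (named list of ROC point data.frames), `scores`
#'   (pooled out-of-fold scores and labels), `folds`, and `details`.
#' @export
runComparison <- function(samples,
                          methods = c("svm-linear", "cnn-only", "cnn-lstm"),
                          scope = "all", k = 5L, seed = 1L,
                          hyper = modelHyper(), augmentRatio = 0,
                          ganCfg = ganConfig()) {
  known <- c("svm-linear", "cnn-only", "cnn-lstm")
  if (!all(methods %in% known))
    stop("config error: unknown method(s) ",
         paste(setdiff(methods, known), collapse = ", "))
  if (!scope %in% c(timepointLevels(), "all"))
    stop("config error: unknown scope '", scope, "'")
  ids <- vapply(samples, subjectId, character(1))
  labs <- vapply(samples, function(s) s@label, integer(1))
  folds <- kfoldSplit(ids, labs, k = k, seed = seed)
  singleTps <- if (scope == "all") timepointLevels() else scope
  rows <- list()
  rocs <- list()
  scores <- list()
  for (method in methods) {
    tps <- if (method == "cnn-lstm") scope else singleTps
    for (tp in tps) {
      key <- paste(method, tp, sep = "@")
      sc <- numeric(length(samples))
      names(sc) <- ids
      foldAcc <- numeric(k)
      for (f in seq_len(k) - 1L) {
        testIdx <- which(folds[ids] == f)
        trainIdx <- which(folds[ids] != f)
        trainS <- samples[trainIdx]
        testS <- samples[testIdx]
        if (method == "svm-linear") {
          tpi <- match(tp, timepointLevels())
          fit <- fitSvm(trainS, tpi)
          sc[testIdx] <- predictSvm(fit, testS, tpi)
        } else {
          if (augmentRatio > 0) {
            cfg <- ganCfg
            cfg$seed <- deriveSeed(seed, paste0("aug-f", f))
            trainS <- augmentSamples(trainS, ratio = augmentRatio,
                                     config = cfg)
          }
          hy <- hyper
          hy$seed <- deriveSeed(seed, paste0(method, "-", tp, "-f", f))
          mdl <- trainModel(trainS, method = method,
                            scope = if (method == "cnn-only") tp else scope,
                            hyper = hy)
          sc[testIdx] <- predictProb(mdl, testS)
        }
        predF <- as.integer(sc[testIdx] >= decisionThreshold(method))
        foldAcc[f + 1L] <- mean(predF == labs[testIdx])
      }
      pred <- as.integer(sc >= decisionThreshold(method))
      cm <- computeMetrics(confusionCounts(labs, pred))
      ra <- rocAuc(sc, labs)
      rows[[key]] <- data.frame(
        method = method, timepoint = tp,
        accuracy = cm$accuracyPct, precision = cm$precisionPct,
        recall = cm$recallPct, auc = ra$auc,
        foldAccMean = 100 * mean(foldAcc), foldAccSd = 100 * stats::sd(foldAcc),
        stringsAsFactors = FALSE)
      rocs[[key]] <- ra$roc
      scores[[key]] <- list(scores = sc, labels = labs)
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       roc = rocs, scores = scores, folds = folds,
       details = list(scope = scope, k = k, seed = seed,
                      methods = methods, augmentRatio = augmentRatio))
}

# SVM scores are margins (threshold 0); neural scores are probabilities
# (threshold 0.5).
decisionThreshold <- function(method) {
  if (method == "svm-linear") 0 else 0.5
}
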