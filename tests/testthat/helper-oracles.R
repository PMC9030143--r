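# Independent reference implementations used as oracles. Each is written
# from the defining formula with explicit loops, deliberately sharing no
# code with the package internals it checks.

# Pearson correlation matrix via explicit mean/deviation loops.
bruteForcePearson <- function(x) {
  Tn <- nrow(x)
  R <- ncol(x)
  mu <- numeric(R)
  for (j in seq_len(R)) {
    s <- 0
    for (t in seq_len(Tn)) s <- s + x[t, j]
    mu[j] <- s / Tn
  }
  sdv <- numeric(R)
  for (j in seq_len(R)) {
    s <- 0
    for (t in seq_len(Tn)) s <- s + (x[t, j] - mu[j])^2
    sdv[j] <- sqrt(s / Tn)
  }
  out <- diag(1, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i != j) {
      cv <- 0
      for (t in seq_len(Tn)) cv <- cv + (x[t, i] - mu[i]) * (x[t, j] - mu[j])
      out[i, j] <- (cv / Tn) / (sdv[i] * sdv[j])
    }
  }
  out
}

# Textbook LSTM cell, scalar-looped, for one sample (vectors x, hPrev, cPrev).
refLstmCell <- function(x, hPrev, cPrev, params) {
  sg <- function(a) 1 / (1 + exp(-a))
  z <- c(hPrev, x)
  H <- length(hPrev)
  gate <- function(W, b, act) {
    out <- numeric(H)
    for (j in seq_len(H)) {
      a <- b[j]
      for (i in seq_along(z)) a <- a + z[i] * W[i, j]
      out[j] <- act(a)
    }
    out
  }
  f <- gate(params$Wf, params$bf, sg)
  i <- gate(params$Wi, params$bi, sg)
  g <- gate(params$Wc, params$bc, tanh)
  o <- gate(params$Wo, params$bo, sg)
  cNew <- f * cPrev + i * g
  list(h = o * tanh(cNew), c = cNew)
}

# AUC by Mann-Whitney pair counting (ties count half).
pairCountAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Brute-force confusion metrics from first principles.
bruteForceMetrics <- function(TP, TN, FP, FN) {
  list(accuracy = (TP + TN) / (TP + TN + FP + FN),
       precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_)
}

# Mean-voxel ROI extraction by explicit voxel loops.
bruteForceRoiMeans <- function(image4d, atlas, dropLeading) {
  d <- dim(image4d)
  R <- max(atlas)
  keep <- (dropLeading + 1):d[1]
  out <- matrix(0, length(keep), R)
  for (ti in seq_along(keep)) {
    for (r in seq_len(R)) {
      vals <- c()
      for (i in seq_len(d[2])) for (j in seq_len(d[3])) for (k in seq_len(d[4]))
        if (atlas[i, j, k] == r)
          vals <- c(vals, image4d[keep[ti], i, j, k])
      out[ti, r] <- mean(vals)
    }
  }
  out
}
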