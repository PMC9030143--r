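#' Configure the residual 1D-CNN spatial feature extractor
#'
#' The per-timepoint extractor consumes the vectorized strict upper
#' triangle of an FC matrix (length R(R-1)/2) as a one-channel 1D signal
#' and applies a stack of convolution blocks (same-padded convolution,
#' ReLU, max-pooling), augmented by exactly two short-connection modules
#' that fuse front-layer features into rear layers: each shortcut pools
#' the source block's output down to the destination's length and projects
#' its channels with a 1x1 convolution before adding it onto the
#' destination input. A global average pool and a linear map produce the
#' embedding handed to the LSTM.
#'
#' @param inputLength length of the edge vector, R(R-1)/2.
#' @param blocks list of integer triples `c(channels, kernel, pool)` per
#'   block; kernels must be odd (same padding).
#' @param shortcuts list of exactly two integer pairs `c(source, dest)`:
#'   the source block's output is added (pooled + 1x1-projected) onto the
#'   input of block `dest`; `dest = length(blocks) + 1` addresses the
#'   final output entering the global pool.
#' @param featureDim embedding size.
#' @param pooling how the final feature map is collapsed before the linear
#'   embedding: `"flatten"` (concatenate positions x channels, the
#'   default: edge identity is informative in connectivity vectors, so
#'   position is preserved) or `"gap"` (global average pooling).
#' @return A validated config list with per-stage lengths and channel
#'   counts resolved; shape mismatches are an error here, at build time.
#' @export
#' @examples
#' cfg <- cnnConfig(inputLength = 190)
#' cfg$lengths
cnnConfig <- function(inputLength,
                      blocks = list(c(16L, 5L, 2L), c(32L, 5L, 2L),
                                    c(64L, 5L, 2L)),
                      shortcuts = list(c(1L, 3L), c(2L, 4L)),
                      featureDim = 64L,
                      pooling = c("flatten", "gap")) {
  pooling <- match.arg(pooling)
  nb <- length(blocks)
  if (length(shortcuts) != 2L)
    stop("config error: exactly two short-connection modules are required")
  chans <- vapply(blocks, function(b) as.integer(b[1L]), integer(1))
  kerns <- vapply(blocks, function(b) as.integer(b[2L]), integer(1))
  pools <- vapply(blocks, function(b) as.integer(b[3L]), integer(1))
  if (any(kerns %% 2L == 0L)) stop("config error: kernels must be odd")
  lens <- integer(nb + 1L)
  lens[1L] <- as.integer(inputLength)
  for (i in seq_len(nb)) {
    lens[i + 1L] <- lens[i] %/% pools[i]
    if (lens[i + 1L] < 1L)
      stop("config error: block ", i, " pools the signal away (length 0)")
  }
  for (s in shortcuts) {
    src <- s[1L]; dst <- s[2L]
    if (src < 1L || dst > nb + 1L || src >= dst)
      stop("config error: shortcut must run forward, 1 <= src < dst <= ",
           nb + 1L)
    # pooling the source by the intervening blocks' pool factors must land
    # exactly on the destination-input length (floor pooling both paths)
    len <- lens[src + 1L]
    for (j in seq_len(dst - 1L)) if (j > src) len <- len %/% pools[j]
    if (len != lens[dst])
      stop("config error: shortcut ", src, "->", dst,
           " cannot be pooled to the destination length")
  }
  list(inputLength = as.integer(inputLength), channels = chans,
       kernels = kerns, pools = pools, shortcuts = shortcuts,
       featureDim = as.integer(featureDim), nBlocks = nb, lengths = lens,
       pooling = pooling)
}

# Channel count entering block i (or the global pool for i = nBlocks + 1).
cnnStageChannels <- function(config, i) {
  if (i == 1L) 1L else config$channels[i - 1L]
}

cnnInitParams <- function(config) {
  nb <- config$nBlocks
  blocks <- lapply(seq_len(nb), function(i) {
    cin <- cnnStageChannels(config, i)
    k <- config$kernels[i]
    list(W = heInit(k * cin, config$channels[i], fanIn = k * cin),
         b = numeric(config$channels[i]))
  })
  shortcuts <- lapply(config$shortcuts, function(s) {
    cin <- config$channels[s[1L]]
    cout <- cnnStageChannels(config, s[2L])
    list(W = heInit(cin, cout, fanIn = cin), b = numeric(cout))
  })
  headIn <- if (config$pooling == "gap") config$channels[nb]
            else config$lengths[nb + 1L] * config$channels[nb]
  head <- list(W = xavierInit(headIn, config$featureDim),
               b = numeric(config$featureDim))
  list(blocks = blocks, shortcuts = shortcuts, head = head)
}

# Pool an activation repeatedly by the intervening blocks' factors, then
# 1x1-project channels; used by the short-connection modules.
shortcutForward <- function(A, nB, config, s, params) {
  src <- s[1L]; dst <- s[2L]
  len <- config$lengths[src + 1L]
  poolCaches <- list()
  for (j in seq_len(dst - 1L)) {
    if (j > src) {
      pc <- poolForward(A, nB, len, config$pools[j])
      A <- pc$out
      len <- pc$Lout
      poolCaches[[length(poolCaches) + 1L]] <- pc
    }
  }
  pj <- proj1x1Forward(A, params$W, params$b)
  list(out = pj$out, proj = pj, poolCaches = poolCaches)
}

shortcutBackward <- function(dout, cache, params) {
  pb <- proj1x1Backward(dout, cache$proj, params$W)
  dA <- pb$dx
  for (pc in rev(cache$poolCaches)) dA <- poolBackward(dA, pc)
  list(dx = dA, grads = list(W = pb$dW, b = pb$db))
}

# Forward pass of the residual CNN on a batch of nB edge vectors.
# x: nB x inputLength matrix. Returns features (nB x featureDim) and,
# when cache = TRUE, everything backward needs.
cnnForwardBatch <- function(x, config, params, cache = FALSE) {
  nB <- nrow(x)
  A <- matrix(t(x), ncol = 1L)   # (L*nB) x 1, position-fastest rows
  nb <- config$nBlocks
  outs <- vector("list", nb)     # post-pool block outputs
  caches <- if (cache) vector("list", nb) else NULL
  scCaches <- vector("list", length(config$shortcuts))
  for (i in seq_len(nb)) {
    for (si in seq_along(config$shortcuts)) {
      if (config$shortcuts[[si]][2L] == i) {
        sc <- shortcutForward(outs[[config$shortcuts[[si]][1L]]], nB, config,
                              config$shortcuts[[si]], params$shortcuts[[si]])
        A <- A + sc$out
        scCaches[[si]] <- sc
      }
    }
    cv <- convForward(A, nB, config$lengths[i], params$blocks[[i]]$W,
                      params$blocks[[i]]$b, config$kernels[i])
    rl <- reluForward(cv$out)
    pl <- poolForward(rl$out, nB, config$lengths[i], config$pools[i])
    A <- pl$out
    outs[[i]] <- A
    if (cache) caches[[i]] <- list(conv = cv, relu = rl, pool = pl)
  }
  for (si in seq_along(config$shortcuts)) {
    if (config$shortcuts[[si]][2L] == nb + 1L) {
      sc <- shortcutForward(outs[[config$shortcuts[[si]][1L]]], nB, config,
                            config$shortcuts[[si]], params$shortcuts[[si]])
      A <- A + sc$out
      scCaches[[si]] <- sc
    }
  }
  gp <- if (config$pooling == "gap") gapForward(A, nB, config$lengths[nb + 1L])
        else flattenForward(A, nB, config$lengths[nb + 1L])
  hd <- denseForward(gp$out, params$head$W, params$head$b)
  # bounded embedding: tanh keeps features in (-1, 1), which stabilizes the
  # recurrent stack consuming them (cell inputs stay in tanh's linear range)
  feat <- tanh(hd$out)
  res <- list(features = feat)
  if (cache)
    res$cache <- list(blocks = caches, shortcuts = scCaches, gap = gp,
                      head = hd, feat = feat, nB = nB)
  res
}

# Backward pass: dFeat is nB x featureDim. Returns gradients in the shape
# of cnnInitParams() plus dx (nB x inputLength).
cnnBackwardBatch <- function(dFeat, config, params, cache) {
  nb <- config$nBlocks
  nB <- cache$nB
  dFeat <- dFeat * (1 - cache$feat * cache$feat)
  hb <- denseBackward(dFeat, cache$head, params$head$W)
  dA <- if (config$pooling == "gap") gapBackward(hb$dx, cache$gap)
        else flattenBackward(hb$dx, cache$gap)
  gBlocks <- vector("list", nb)
  gShort <- vector("list", length(config$shortcuts))
  # accumulated gradient w.r.t. each block's (post-pool) output; index 0 = input
  dOuts <- vector("list", nb + 1L)
  dOuts[[nb + 1L]] <- dA   # slot i+1 holds d(out_i); slot 1 holds d(input)
  addTo <- function(lst, i, v) {
    if (is.null(lst[[i]])) lst[[i]] <- v else lst[[i]] <- lst[[i]] + v
    lst
  }
  for (si in seq_along(config$shortcuts)) {
    s <- config$shortcuts[[si]]
    if (s[2L] == nb + 1L) {
      sb <- shortcutBackward(dA, cache$shortcuts[[si]],
                             params$shortcuts[[si]])
      gShort[[si]] <- sb$grads
      dOuts <- addTo(dOuts, s[1L] + 1L, sb$dx)
    }
  }
  for (i in rev(seq_len(nb))) {
    dOut <- dOuts[[i + 1L]]
    dRelu <- poolBackward(dOut, cache$blocks[[i]]$pool)
    dConvOut <- reluBackward(dRelu, cache$blocks[[i]]$relu)
    cb <- convBackward(dConvOut, cache$blocks[[i]]$conv,
                       params$blocks[[i]]$W)
    gBlocks[[i]] <- list(W = cb$dW, b = cb$db)
    dPre <- cb$dx
    dOuts <- addTo(dOuts, i, dPre)
    for (si in seq_along(config$shortcuts)) {
      s <- config$shortcuts[[si]]
      if (s[2L] == i) {
        sb <- shortcutBackward(dPre, cache$shortcuts[[si]],
                               params$shortcuts[[si]])
        gShort[[si]] <- sb$grads
        dOuts <- addTo(dOuts, s[1L] + 1L, sb$dx)
      }
    }
  }
  dx <- t(matrix(dOuts[[1L]], config$inputLength, nB))
  list(grads = list(blocks = gBlocks, shortcuts = gShort,
                    head = list(W = hb$dW, b = hb$db)),
       dx = dx)
}

#' Run the residual CNN on one FC matrix
#'
#' Vectorizes the FC matrix's strict upper triangle row-major, runs the
#' convolutional extractor, and returns the embedding. Inference is
#' deterministic: two calls with the same parameters and input agree
#' exactly.
#'
#' @param fc an [FCMatrix-class] (or an edge vector of length
#'   `config$inputLength`).
#' @param config a [cnnConfig()] object.
#' @param params parameters as produced by model training (or
#'   `cnnInitParams` internally).
#' @return Numeric vector of length `config$featureDim`.
#' @export
cnnForward <- function(fc, config, params) {
  v <- if (is(fc, "FCMatrix")) upperTriVec(fc) else as.numeric(fc)
  if (length(v) != config$inputLength)
    stop("input error: edge vector length ", length(v),
         " does not match config inputLength ", config$inputLength)
  drop(cnnForwardBatch(matrix(v, 1L), config, params)$features)
}
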