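#' One LSTM cell step
#'
#' Applies the standard gated recurrence to one input: with z the
#' concatenation \[h_prev, x\],
#' forget gate f = sigma(z W_f + b_f), input gate i = sigma(z W_i + b_i),
#' candidate state c~ = tanh(z W_c + b_c), cell state
#' c = f * c_prev + i * c~, output gate o = sigma(z W_o + b_o), and hidden
#' state h = o * tanh(c), all products elementwise. Weight matrices act on
#' the concatenated vector, so each decomposes into recurrent and input
#' blocks W = \[W_h; W_x\].
#'
#' @param x input, a numeric vector (one sample) or a batch matrix B x d.
#' @param hPrev,cPrev previous hidden and cell state, vector of length H or
#'   matrix B x H.
#' @param params list with matrices `Wf`, `Wi`, `Wc`, `Wo` (each
#'   (H + d) x H, rows ordered \[h, x\]) and bias vectors `bf`, `bi`, `bc`,
#'   `bo` (length H); see [lstmInitParams()].
#' @return List with `h` and `c` (same shape as `hPrev`) and the gate
#'   activations `f`, `i`, `o`, `g` (the candidate c~).
#' @export
#' @examples
#' p <- lstmInitParams(inputDim = 2, hidden = 3)
#' st <- lstmCellStep(c(0.1, -0.2), numeric(3), numeric(3), p)
#' st$h
lstmCellStep <- function(x, hPrev, cPrev, params) {
  vec <- is.null(dim(x))
  if (vec) {
    x <- matrix(x, 1L)
    hPrev <- matrix(hPrev, 1L)
    cPrev <- matrix(cPrev, 1L)
  }
  H <- ncol(hPrev)
  if (nrow(params$Wf) != H + ncol(x))
    stop("config error: weight rows (", nrow(params$Wf),
         ") must equal hidden + input dim (", H + ncol(x), ")")
  z <- cbind(hPrev, x)
  nb <- nrow(z)
  f <- sigmoidFn(z %*% params$Wf + rep(params$bf, each = nb))
  i <- sigmoidFn(z %*% params$Wi + rep(params$bi, each = nb))
  g <- tanh(z %*% params$Wc + rep(params$bc, each = nb))
  o <- sigmoidFn(z %*% params$Wo + rep(params$bo, each = nb))
  cNew <- f * cPrev + i * g
  h <- o * tanh(cNew)
  if (vec) {
    list(h = drop(h), c = drop(cNew), f = drop(f), i = drop(i),
         o = drop(o), g = drop(g))
  } else {
    list(h = h, c = cNew, f = f, i = i, o = o, g = g)
  }
}

#' Initialize LSTM cell parameters
#'
#' Xavier-scaled gaussian weights; the forget-gate bias starts at 1 so the
#' cell initially retains its state (standard practice).
#'
#' @param inputDim input dimension d.
#' @param hidden hidden size H.
#' @return Parameter list as consumed by [lstmCellStep()].
#' @export
lstmInitParams <- function(inputDim, hidden) {
  nIn <- hidden + inputDim
  list(Wf = xavierInit(nIn, hidden), Wi = xavierInit(nIn, hidden),
       Wc = xavierInit(nIn, hidden), Wo = xavierInit(nIn, hidden),
       bf = rep(1, hidden), bi = numeric(hidden), bc = numeric(hidden),
       bo = numeric(hidden))
}

# Forward over a sequence: xs is a list of T matrices (B x d). Returns the
# per-step hidden states plus caches for BPTT.
lstmLayerForward <- function(xs, params) {
  Tn <- length(xs)
  nb <- nrow(xs[[1L]])
  H <- ncol(params$Wf)
  h <- matrix(0, nb, H)
  cc <- matrix(0, nb, H)
  hs <- vector("list", Tn)
  caches <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    st <- lstmCellStep(xs[[t]], h, cc, params)
    caches[[t]] <- list(z = cbind(h, xs[[t]]), f = st$f, i = st$i,
                        o = st$o, g = st$g, cPrev = cc, cNew = st$c)
    h <- st$h
    cc <- st$c
  }
  list(hs = lapply(caches, function(ca) ca$o * tanh(ca$cNew)),
       caches = caches, H = H, inputDim = ncol(xs[[1L]]))
}

# Backward through time for one layer. dhs: list of T gradients w.r.t. the
# layer's hidden outputs coming from above (NULL entries mean zero).
lstmLayerBackward <- function(dhs, fwd, params) {
  Tn <- length(fwd$caches)
  H <- fwd$H
  d <- fwd$inputDim
  nb <- nrow(fwd$caches[[1L]]$z)
  grads <- treeZero(params)
  dhNext <- matrix(0, nb, H)
  dcNext <- matrix(0, nb, H)
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    ca <- fwd$caches[[t]]
    dh <- dhNext
    if (!is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    tc <- tanh(ca$cNew)
    do <- dh * tc
    dc <- dcNext + dh * ca$o * (1 - tc * tc)
    df <- dc * ca$cPrev
    di <- dc * ca$g
    dg <- dc * ca$i
    dcNext <- dc * ca$f
    dzf <- df * ca$f * (1 - ca$f)
    dzi <- di * ca$i * (1 - ca$i)
    dzg <- dg * (1 - ca$g * ca$g)
    dzo <- do * ca$o * (1 - ca$o)
    grads$Wf <- grads$Wf + crossprod(ca$z, dzf)
    grads$Wi <- grads$Wi + crossprod(ca$z, dzi)
    grads$Wc <- grads$Wc + crossprod(ca$z, dzg)
    grads$Wo <- grads$Wo + crossprod(ca$z, dzo)
    grads$bf <- grads$bf + colSums(dzf)
    grads$bi <- grads$bi + colSums(dzi)
    grads$bc <- grads$bc + colSums(dzg)
    grads$bo <- grads$bo + colSums(dzo)
    dz <- dzf %*% t(params$Wf) + dzi %*% t(params$Wi) +
      dzg %*% t(params$Wc) + dzo %*% t(params$Wo)
    dhNext <- dz[, seq_len(H), drop = FALSE]
    dxs[[t]] <- dz[, H + seq_len(d), drop = FALSE]
  }
  list(dxs = dxs, grads = grads)
}

# Forward through the full stack with optional inter-layer dropout masks
# (inverted dropout; masks[[l]] scales the input to layer l + 1, shared
# across timesteps). Returns top-layer last hidden state plus caches.
lstmStackForward <- function(feats, layers, masks = NULL) {
  xs <- feats
  fwds <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    if (l > 1L && !is.null(masks)) {
      m <- masks[[l - 1L]]
      xs <- lapply(xs, function(x) x * m)
    }
    fwds[[l]] <- lstmLayerForward(xs, layers[[l]])
    xs <- fwds[[l]]$hs
  }
  list(hTop = xs[[length(xs)]], fwds = fwds)
}

# Backward through the stack. dhTop: gradient w.r.t. the top layer's last
# hidden state. Returns per-layer grads and gradients w.r.t. the feature
# sequence.
lstmStackBackward <- function(dhTop, stackFwd, layers, masks = NULL) {
  nL <- length(layers)
  Tn <- length(stackFwd$fwds[[1L]]$caches)
  gradsLayers <- vector("list", nL)
  dhs <- vector("list", Tn)
  dhs[[Tn]] <- dhTop
  for (l in rev(seq_len(nL))) {
    lb <- lstmLayerBackward(dhs, stackFwd$fwds[[l]], layers[[l]])
    gradsLayers[[l]] <- lb$grads
    dhs <- lb$dxs
    if (l > 1L && !is.null(masks)) {
      m <- masks[[l - 1L]]
      dhs <- lapply(dhs, function(dx) dx * m)
    }
  }
  list(grads = gradsLayers, dFeats = dhs)
}
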