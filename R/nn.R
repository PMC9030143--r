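# Neural-network primitives: vectorized forward/backward passes for the
# layers the classifier and the GAN are built from, plus Adam and small
# utilities over nested parameter lists ("trees").
#
# Activation layout convention for convolutional stages: a (L*B) x C matrix
# whose row index is position-fastest, i.e. row = (b-1)*L + l. This makes
# array(A, c(L, B, C)) the natural 3D view and keeps every layer a single
# matrix operation plus a handful of slice copies (im2col).

sigmoidFn <- function(x) 1 / (1 + exp(-x))

# ---- parameter trees ------------------------------------------------------

treeMap <- function(f, x) {
  if (is.numeric(x)) f(x) else lapply(x, function(e) treeMap(f, e))
}

treeMap2 <- function(f, x, y) {
  if (is.numeric(x)) f(x, y)
  else Map(function(a, b) treeMap2(f, a, b), x, y)
}

treeZero <- function(x) treeMap(function(v) v * 0, x)

adamInit <- function(params) {
  list(m = treeZero(params), v = treeZero(params), t = 0L)
}

# Adam with optional decoupled weight decay (the AdamW scheme: decay is
# applied directly to the parameters, not mixed into the moment estimates).
adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.numeric(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      list(p = p * (1 - lr * weightDecay) -
             lr * (m / c1) / (sqrt(v / c2) + eps), m = m, v = v)
    } else {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# ---- dense ----------------------------------------------------------------

denseForward <- function(x, W, b) {
  list(out = x %*% W + rep(b, each = nrow(x)), x = x)
}

denseBackward <- function(dout, cache, W) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

# ---- elementwise ----------------------------------------------------------

reluForward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

reluBackward <- function(dout, cache) dout * cache$mask

# ---- 1D convolution, stride 1, zero "same" padding ------------------------

# Gather-index vectors depend only on layer geometry, not on data; cache
# them per (operation, geometry) so the training loop never rebuilds them.
.idxCache <- new.env(parent = emptyenv())

cachedIdx <- function(key, gen) {
  v <- .idxCache[[key]]
  if (is.null(v)) {
    v <- gen()
    assign(key, v, envir = .idxCache)
  }
  v
}

convIdx <- function(L, nB, k) {
  p <- (k - 1L) %/% 2L
  Lp <- L + 2L * p
  cachedIdx(paste("conv", L, nB, k), function() {
    base <- (seq_len(nB) - 1L) * Lp
    list(insIdx = as.vector(outer(p + seq_len(L), base, "+")),
         idxs = lapply(seq_len(k), function(j)
           as.vector(outer(seq.int(j, length.out = L), base, "+"))),
         Lp = Lp)
  })
}

convForward <- function(A, nB, L, W, b, k) {
  Cin <- ncol(A)
  ix <- convIdx(L, nB, k)
  Ap <- matrix(0, ix$Lp * nB, Cin)
  Ap[ix$insIdx, ] <- A
  M <- matrix(0, L * nB, k * Cin)
  for (j in seq_len(k))
    M[, ((j - 1L) * Cin + 1L):(j * Cin)] <- Ap[ix$idxs[[j]], , drop = FALSE]
  out <- M %*% W + rep(b, each = L * nB)
  list(out = out, M = M, L = L, nB = nB, Cin = Cin, k = k, ix = ix)
}

convBackward <- function(dout, cache, W) {
  k <- cache$k; L <- cache$L; nB <- cache$nB; Cin <- cache$Cin
  ix <- cache$ix
  dW <- crossprod(cache$M, dout)
  db <- colSums(dout)
  dM <- dout %*% t(W)
  dAp <- matrix(0, ix$Lp * nB, Cin)
  for (j in seq_len(k)) {
    idx <- ix$idxs[[j]]
    dAp[idx, ] <- dAp[idx, , drop = FALSE] +
      dM[, ((j - 1L) * Cin + 1L):(j * Cin)]
  }
  list(dx = dAp[ix$insIdx, , drop = FALSE], dW = dW, db = db)
}

# 1x1 convolution (channel projection) is a plain position-wise dense map.
proj1x1Forward <- function(A, W, b) denseForward(A, W, b)
proj1x1Backward <- function(dout, cache, W) denseBackward(dout, cache, W)

# ---- max pooling, stride == width, floor truncation -----------------------

# Row indices of positions (o, o+pool, ...) for every sample in the batch,
# in the (position-fastest) activation layout.
poolRowIdx <- function(o, pool, Lout, L, nB) {
  cachedIdx(paste("pool", o, pool, Lout, L, nB), function()
    as.vector(outer(seq.int(o, by = pool, length.out = Lout),
                    (seq_len(nB) - 1L) * L, "+")))
}

poolForward <- function(A, nB, L, pool) {
  Lout <- L %/% pool
  out <- A[poolRowIdx(1L, pool, Lout, L, nB), , drop = FALSE]
  amax <- matrix(1L, nrow(out), ncol(out))
  if (pool > 1L) {
    for (o in 2L:pool) {
      s <- A[poolRowIdx(o, pool, Lout, L, nB), , drop = FALSE]
      upd <- (s > out) + 0L
      out <- out + (s - out) * upd
      amax <- amax + (o - amax) * upd
    }
  }
  list(out = out, amax = amax, L = L, nB = nB, pool = pool, Lout = Lout)
}

poolBackward <- function(dout, cache) {
  L <- cache$L; nB <- cache$nB
  Lout <- cache$Lout
  dX <- matrix(0, L * nB, ncol(dout))
  for (o in seq_len(cache$pool)) {
    idx <- poolRowIdx(o, cache$pool, Lout, L, nB)
    dX[idx, ] <- dout * (cache$amax == o)
  }
  dX
}

# ---- global average pooling over positions --------------------------------

gapForward <- function(A, nB, L) {
  list(out = colMeans(array(A, c(L, nB, ncol(A)))), L = L, nB = nB)
}

gapBackward <- function(dout, cache) {
  L <- cache$L
  matrix(array(rep(dout / L, each = L),
               c(L, cache$nB, ncol(dout))), L * cache$nB, ncol(dout))
}

# ---- flatten positions x channels into one feature row per sample ---------

flattenForward <- function(A, nB, L) {
  C <- ncol(A)
  list(out = t(matrix(aperm(array(A, c(L, nB, C)), c(1L, 3L, 2L)),
                      L * C, nB)),
       L = L, nB = nB, C = C)
}

flattenBackward <- function(dout, cache) {
  X <- aperm(array(t(dout), c(cache$L, cache$C, cache$nB)), c(1L, 3L, 2L))
  matrix(X, cache$L * cache$nB, cache$C)
}

# ---- initializers (He for ReLU paths, Xavier elsewhere) -------------------

heInit <- function(nr, nc, fanIn = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
}

xavierInit <- function(nr, nc, fanIn = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(1 / fanIn)), nr, nc)
}
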