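# Native neural-network primitives: dense, 1-D convolution, 1-D transposed
# convolution, LSTM, and Adam.  Every layer provides a forward pass that
# returns a cache and a backward pass returning parameter gradients and the
# gradient with respect to its input.  Batches are stored channel-major:
# signals as C x T x B arrays, feature vectors as features x B matrices.
# Matrix products go through BLAS; the only R-level loops are over the
# kernel taps (9 iterations) and LSTM time steps.

glorot <- function(n_out, n_in, fan_in = n_in, fan_out = n_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

## ---- dense ----------------------------------------------------------------

dense_init <- function(n_in, n_out) {
  list(W = glorot(n_out, n_in), b = numeric(n_out))
}

# X: n_in x B -> n_out x B  (column-major recycling adds b per row)
dense_fwd <- function(W, b, X) W %*% X + b

dense_bwd <- function(W, X, dY) {
  list(dW = dY %*% t(X), db = rowSums(dY), dX = crossprod(W, dY))
}

## ---- 1-D convolution ------------------------------------------------------

# Stride-s convolution with kernel K and asymmetric padding chosen so that
# T_out = T / s exactly (requires T %% s == 0): pad_l = floor((K-s)/2),
# pad_r = K - s - pad_l.  Weights are stored c_out x (C*K) with column
# index c + C*(k-1).

conv_pads <- function(K, stride) {
  tot <- K - stride
  stopifnot(tot >= 0)
  c(tot %/% 2L, tot - tot %/% 2L)
}

conv1d_init <- function(c_in, c_out, K) {
  list(W = glorot(c_out, c_in * K, fan_in = c_in * K, fan_out = c_out * K),
       b = numeric(c_out))
}

# Forward/backward of the strided convolution run in compiled code
# (src/kernels.cpp); these wrappers own the padding arithmetic and cache.
conv1d_fwd <- function(W, b, X, stride, K) {
  d <- dim(X)
  stopifnot(d[2L] %% stride == 0L)
  pads <- conv_pads(K, stride)
  out <- .conv1d_fwd_cpp(W, b, X, stride, K, pads[1L], pads[2L])
  list(Y = out$Y,
       cache = list(P = out$P, dimX = d, pads = pads, K = K,
                    stride = stride))
}

conv1d_bwd <- function(W, cache, dY) {
  out <- .conv1d_bwd_cpp(W, cache$P, dY, cache$dimX[1L], cache$dimX[2L],
                         cache$stride, cache$K, cache$pads[1L])
  list(dW = out$dW, db = as.numeric(out$db), dX = out$dX)
}

## ---- 1-D transposed convolution --------------------------------------------

# Exact adjoint of the convolution above: upsamples T -> T * stride with the
# same kernel/padding convention.  Weights c_out x (c_in*K), column index
# c_in + c_in_total*(k-1).

convtr1d_init <- function(c_in, c_out, K) {
  list(W = glorot(c_out, c_in * K, fan_in = c_in, fan_out = c_out * K),
       b = numeric(c_out))
}

convtr1d_fwd <- function(W, b, X, stride, K) {
  d <- dim(X); C <- d[1L]; Tin <- d[2L]; B <- d[3L]
  c_out <- nrow(W)
  pads <- conv_pads(K, stride)
  Tfull <- (Tin - 1L) * stride + K
  Tout <- Tin * stride
  Xm <- matrix(X, C, Tin * B)
  Yfull <- array(0, c(c_out, Tfull, B))
  pos <- seq.int(1L, by = stride, length.out = Tin)
  for (k in seq_len(K)) {
    Wk <- W[, (k - 1L) * C + seq_len(C), drop = FALSE]
    cols <- pos + (k - 1L)
    Yfull[, cols, ] <- Yfull[, cols, , drop = FALSE] +
      array(Wk %*% Xm, c(c_out, Tin, B))
  }
  Y <- Yfull[, pads[1L] + seq_len(Tout), , drop = FALSE]
  Ym <- matrix(Y, c_out, Tout * B) + b
  list(Y = array(Ym, c(c_out, Tout, B)),
       cache = list(Xm = Xm, dimX = d, pads = pads, pos = pos, K = K,
                    stride = stride, Tfull = Tfull, Tout = Tout))
}

convtr1d_bwd <- function(W, cache, dY) {
  d <- dim(dY); c_out <- d[1L]; Tout <- d[2L]; B <- d[3L]
  C <- cache$dimX[1L]; Tin <- cache$dimX[2L]
  dYfull <- array(0, c(c_out, cache$Tfull, B))
  dYfull[, cache$pads[1L] + seq_len(Tout), ] <- dY
  dXm <- matrix(0, C, Tin * B)
  dW <- matrix(0, c_out, C * cache$K)
  for (k in seq_len(cache$K)) {
    cols <- cache$pos + (k - 1L)
    dYk <- matrix(dYfull[, cols, ], c_out, Tin * B)
    Wk <- W[, (k - 1L) * C + seq_len(C), drop = FALSE]
    dXm <- dXm + crossprod(Wk, dYk)
    dW[, (k - 1L) * C + seq_len(C)] <- dYk %*% t(cache$Xm)
  }
  list(dW = dW, db = rowSums(matrix(dY, c_out, Tout * B)),
       dX = array(dXm, cache$dimX))
}

## ---- LSTM -------------------------------------------------------------------

# Single-layer LSTM over a short sequence; gates ordered (i, f, g, o).
# W: 4m x (n_in + m), b: 4m; initial state zero.

lstm_init <- function(n_in, m) {
  W <- glorot(4L * m, n_in + m)
  b <- numeric(4L * m)
  b[m + seq_len(m)] <- 1  # forget-gate bias
  list(W = W, b = b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_fwd <- function(W, b, X) {
  d <- dim(X); n_in <- d[1L]; T0 <- d[2L]; B <- d[3L]
  m <- nrow(W) %/% 4L
  h <- matrix(0, m, B); cs <- matrix(0, m, B)
  H <- array(0, c(m, T0, B))
  steps <- vector("list", T0)
  i_idx <- seq_len(m); f_idx <- m + i_idx; g_idx <- 2L * m + i_idx
  o_idx <- 3L * m + i_idx
  for (t in seq_len(T0)) {
    xt <- matrix(X[, t, ], n_in, B)
    inp <- rbind(xt, h)
    A <- W %*% inp + b
    i_g <- sigmoid(A[i_idx, , drop = FALSE])
    f_g <- sigmoid(A[f_idx, , drop = FALSE])
    g_g <- tanh(A[g_idx, , drop = FALSE])
    o_g <- sigmoid(A[o_idx, , drop = FALSE])
    c_prev <- cs
    cs <- f_g * c_prev + i_g * g_g
    tc <- tanh(cs)
    h <- o_g * tc
    H[, t, ] <- h
    steps[[t]] <- list(inp = inp, i = i_g, f = f_g, g = g_g, o = o_g,
                       c_prev = c_prev, c = cs, tc = tc)
  }
  list(Y = H, cache = list(steps = steps, dimX = d, m = m))
}

lstm_bwd <- function(W, cache, dH) {
  d <- cache$dimX; n_in <- d[1L]; T0 <- d[2L]; B <- d[3L]
  m <- cache$m
  dW <- matrix(0, 4L * m, n_in + m); db <- numeric(4L * m)
  dX <- array(0, d)
  dh_next <- matrix(0, m, B); dc_next <- matrix(0, m, B)
  i_idx <- seq_len(m); f_idx <- m + i_idx; g_idx <- 2L * m + i_idx
  o_idx <- 3L * m + i_idx
  for (t in rev(seq_len(T0))) {
    st <- cache$steps[[t]]
    dh <- matrix(dH[, t, ], m, B) + dh_next
    do_g <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dA <- rbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_g * st$o * (1 - st$o))
    dW <- dW + dA %*% t(st$inp)
    db <- db + rowSums(dA)
    dinp <- crossprod(W, dA)
    dX[, t, ] <- dinp[seq_len(n_in), ]
    dh_next <- dinp[n_in + seq_len(m), , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

## ---- Adam -------------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}
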