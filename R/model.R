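# The semi-supervised variational autoencoder (SVAE).
#
# Encoder: a stack of strided 1-D convolutions (kernel 9, stride 4, tanh)
# followed by dense layers and two linear heads producing the Gaussian
# posterior (mu, log sigma) over the latent code z.  The latent code is
# sampled with the reparameterization z = mu + sigma * eps and feeds both a
# small dense prediction head (speed, km/h) and one of two decoders:
#
#   * "sine"      - the weighted sine-wave decoder: three affine maps send z
#                   to per-channel amplitudes A (C x H), shared angular
#                   frequencies Omega (H) and phases Phi (H); the
#                   reconstruction is X[c, tau] = sum_k A[c,k] *
#                   sin(Omega[k] * tau + Phi[k]) over the T centred sample
#                   offsets tau.
#   * "lstm_cnn"  - dense seed sequence -> LSTM -> stack of transposed
#                   convolutions mirroring the encoder.
#
# The joint training loss is alpha * prediction-MSE + reconstruction-MSE +
# beta * KL(q(z|X) || N(0, I)); one shared eps draw is used by the
# prediction and reconstruction terms.

#' SVAE architecture configuration
#'
#' Grid-valued fields default to the smallest values of the search grids
#' ([svae_search_space()]); any positive value is accepted so that reduced
#' toy models can be built in tests.
#'
#' @param conv_channels channels of each encoder convolution layer.
#' @param hidden_size width of the encoder dense layers.
#' @param hidden_depth number of encoder dense layers (1 or 2).
#' @param latent length L of the latent code.
#' @param decoder `"sine"` or `"lstm_cnn"`.
#' @param sine_components number H of sine components of the sine decoder.
#' @param n_conv number of strided convolution layers (window length must be
#'   divisible by `conv_stride^n_conv`).
#' @param conv_kernel,conv_stride kernel width and stride of each
#'   convolution layer.
#' @param head_hidden width of the hidden layer of the speed-prediction
#'   head.
#' @param tau_normalized if `TRUE` the sine-decoder time axis is scaled to
#'   `[-1, 1)` instead of raw centred integer sample offsets.
#' @return an object of class `svae_config`.
#' @export
svae_config <- function(conv_channels = 4L, hidden_size = 128L,
                        hidden_depth = 1L, latent = 64L,
                        decoder = c("sine", "lstm_cnn"),
                        sine_components = 10L, n_conv = 3L,
                        conv_kernel = 9L, conv_stride = 4L,
                        head_hidden = 32L, tau_normalized = FALSE) {
  decoder <- match.arg(decoder)
  stopifnot(conv_channels >= 1, hidden_size >= 1, hidden_depth %in% 1:2,
            latent >= 1, sine_components >= 1, n_conv >= 1,
            conv_kernel > conv_stride)
  structure(list(conv_channels = as.integer(conv_channels),
                 hidden_size = as.integer(hidden_size),
                 hidden_depth = as.integer(hidden_depth),
                 latent = as.integer(latent), decoder = decoder,
                 sine_components = as.integer(sine_components),
                 n_conv = as.integer(n_conv),
                 conv_kernel = as.integer(conv_kernel),
                 conv_stride = as.integer(conv_stride),
                 head_hidden = as.integer(head_hidden),
                 tau_normalized = isTRUE(tau_normalized)),
            class = "svae_config")
}

#' Initialize an SVAE model
#'
#' @param n_channels number of input channels C.
#' @param window_len window length T in samples; must be divisible by
#'   `conv_stride^n_conv`.
#' @param cfg an [svae_config()].
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `svae_model` holding the parameter list, the
#'   configuration and the input/label normalization (identity until
#'   [train_model()] fits it).
#' @export
svae_init <- function(n_channels, window_len, cfg = svae_config(),
                      seed = NULL) {
  stopifnot(inherits(cfg, "svae_config"))
  if (!is.null(seed)) set.seed(seed)
  sr <- cfg$conv_stride^cfg$n_conv
  if (window_len %% sr != 0L)
    stop("window length ", window_len, " is not divisible by stride^n_conv = ", sr)
  T3 <- window_len %/% sr
  if (T3 < 1L) stop("window too short for ", cfg$n_conv, " conv layers")
  c_ch <- cfg$conv_channels
  par <- list()
  c_in <- n_channels
  for (i in seq_len(cfg$n_conv)) {
    l <- conv1d_init(c_in, c_ch, cfg$conv_kernel)
    par[[paste0("enc.conv", i, ".W")]] <- l$W
    par[[paste0("enc.conv", i, ".b")]] <- l$b
    c_in <- c_ch
  }
  flat <- c_ch * T3
  d_in <- flat
  for (i in seq_len(cfg$hidden_depth)) {
    l <- dense_init(d_in, cfg$hidden_size)
    par[[paste0("enc.fc", i, ".W")]] <- l$W
    par[[paste0("enc.fc", i, ".b")]] <- l$b
    d_in <- cfg$hidden_size
  }
  l <- dense_init(cfg$hidden_size, cfg$latent)
  par[["enc.mu.W"]] <- l$W; par[["enc.mu.b"]] <- l$b
  l <- dense_init(cfg$hidden_size, cfg$latent)
  par[["enc.ls.W"]] <- l$W
  par[["enc.ls.b"]] <- l$b - 1  # start with sigma ~ exp(-1)
  l <- dense_init(cfg$latent, cfg$head_hidden)
  par[["head.h1.W"]] <- l$W; par[["head.h1.b"]] <- l$b
  l <- dense_init(cfg$head_hidden, 1L)
  par[["head.h2.W"]] <- l$W; par[["head.h2.b"]] <- l$b
  if (cfg$decoder == "sine") {
    H <- cfg$sine_components
    l <- dense_init(cfg$latent, n_channels * H)
    par[["dec.W1"]] <- l$W; par[["dec.b1"]] <- l$b
    l <- dense_init(cfg$latent, H)
    par[["dec.W2"]] <- l$W * 0.1
    # spread initial frequencies over the plausible gait band (rad/sample)
    fr <- stats::runif(H, 0.006, 0.3)
    par[["dec.b2"]] <- if (cfg$tau_normalized) fr * (window_len / 2) else fr
    l <- dense_init(cfg$latent, H)
    par[["dec.W3"]] <- l$W * 0.1; par[["dec.b3"]] <- l$b
  } else {
    l <- dense_init(cfg$latent, cfg$hidden_size)
    par[["dec.in.W"]] <- l$W; par[["dec.in.b"]] <- l$b
    l <- dense_init(cfg$hidden_size, c_ch * T3)
    par[["dec.seq.W"]] <- l$W; par[["dec.seq.b"]] <- l$b
    l <- lstm_init(c_ch, c_ch)
    par[["dec.lstm.W"]] <- l$W; par[["dec.lstm.b"]] <- l$b
    c_in <- c_ch
    for (i in seq_len(cfg$n_conv)) {
      c_out <- if (i == cfg$n_conv) n_channels else c_ch
      l <- convtr1d_init(c_in, c_out, cfg$conv_kernel)
      par[[paste0("dec.tr", i, ".W")]] <- l$W
      par[[paste0("dec.tr", i, ".b")]] <- l$b
      c_in <- c_out
    }
  }
  structure(list(par = par, cfg = cfg, n_channels = as.integer(n_channels),
                 window_len = as.integer(window_len), T3 = T3,
                 norm = list(ch_mean = numeric(n_channels),
                             ch_sd = rep(1, n_channels),
                             y_mean = 0, y_sd = 1)),
            class = "svae_model")
}

#' @export
print.svae_model <- function(x, ...) {
  cat(sprintf(
    "<svae_model> %d ch x %d samples; conv %d x%d, hidden %d x%d, latent %d, decoder %s%s\n",
    x$n_channels, x$window_len, x$cfg$conv_channels, x$cfg$n_conv,
    x$cfg$hidden_size, x$cfg$hidden_depth, x$cfg$latent, x$cfg$decoder,
    if (x$cfg$decoder == "sine")
      sprintf(" (H = %d)", x$cfg$sine_components) else ""))
  cat(sprintf("  parameters: %d\n",
              sum(vapply(x$par, length, integer(1)))))
  invisible(x)
}

as_batch <- function(X, C, T_len) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  stopifnot(length(dim(X)) == 3L, dim(X)[1L] == C, dim(X)[2L] == T_len)
  X
}

standardize_X <- function(model, X) {
  (X - model$norm$ch_mean) / model$norm$ch_sd  # recycles over channel dim
}

## ---- encoder ---------------------------------------------------------------

LOGSIG_MIN <- -10
LOGSIG_MAX <- 6

encoder_fwd <- function(model, X) {
  cfg <- model$cfg
  par <- model$par
  B <- dim(X)[3L]
  cur <- X
  conv_caches <- vector("list", cfg$n_conv)
  conv_acts <- vector("list", cfg$n_conv)
  for (i in seq_len(cfg$n_conv)) {
    f <- conv1d_fwd(par[[paste0("enc.conv", i, ".W")]],
                    par[[paste0("enc.conv", i, ".b")]],
                    cur, cfg$conv_stride, cfg$conv_kernel)
    cur <- tanh(f$Y)
    conv_caches[[i]] <- f$cache
    conv_acts[[i]] <- cur
  }
  flat_dim <- prod(dim(cur)[1:2])
  h <- matrix(cur, flat_dim, B)
  fc_in <- vector("list", cfg$hidden_depth)
  fc_act <- vector("list", cfg$hidden_depth)
  for (i in seq_len(cfg$hidden_depth)) {
    fc_in[[i]] <- h
    h <- tanh(dense_fwd(par[[paste0("enc.fc", i, ".W")]],
                        par[[paste0("enc.fc", i, ".b")]], h))
    fc_act[[i]] <- h
  }
  mu <- dense_fwd(par[["enc.mu.W"]], par[["enc.mu.b"]], h)
  ls_raw <- dense_fwd(par[["enc.ls.W"]], par[["enc.ls.b"]], h)
  ls <- ls_raw
  ls[ls < LOGSIG_MIN] <- LOGSIG_MIN
  ls[ls > LOGSIG_MAX] <- LOGSIG_MAX
  list(mu = mu, logsig = ls,
       cache = list(conv = conv_caches, conv_acts = conv_acts,
                    fc_in = fc_in, fc_act = fc_act, h = h,
                    ls_mask = (ls_raw > LOGSIG_MIN & ls_raw < LOGSIG_MAX) * 1,
                    conv_out_dim = dim(conv_acts[[cfg$n_conv]])))
}

encoder_bwd <- function(model, cache, dmu, dls) {
  cfg <- model$cfg
  par <- model$par
  g <- list()
  dls <- dls * cache$ls_mask
  bm <- dense_bwd(par[["enc.mu.W"]], cache$h, dmu)
  g[["enc.mu.W"]] <- bm$dW; g[["enc.mu.b"]] <- bm$db
  bl <- dense_bwd(par[["enc.ls.W"]], cache$h, dls)
  g[["enc.ls.W"]] <- bl$dW; g[["enc.ls.b"]] <- bl$db
  dh <- bm$dX + bl$dX
  for (i in rev(seq_len(cfg$hidden_depth))) {
    dpre <- dh * (1 - cache$fc_act[[i]]^2)
    bf <- dense_bwd(par[[paste0("enc.fc", i, ".W")]], cache$fc_in[[i]], dpre)
    g[[paste0("enc.fc", i, ".W")]] <- bf$dW
    g[[paste0("enc.fc", i, ".b")]] <- bf$db
    dh <- bf$dX
  }
  dcur <- array(dh, cache$conv_out_dim)
  for (i in rev(seq_len(cfg$n_conv))) {
    dpre <- dcur * (1 - cache$conv_acts[[i]]^2)
    bc <- conv1d_bwd(par[[paste0("enc.conv", i, ".W")]], cache$conv[[i]], dpre)
    g[[paste0("enc.conv", i, ".W")]] <- bc$dW
    g[[paste0("enc.conv", i, ".b")]] <- bc$db
    dcur <- bc$dX
  }
  list(grads = g, dX = dcur)
}

## ---- latent code ------------------------------------------------------------

#' Construct a latent code (Gaussian posterior parameters)
#'
#' @param mu posterior mean vector (length L) or L x B matrix.
#' @param sigma posterior standard deviation, strictly positive, same shape
#'   as `mu`.  Stored internally as `log(sigma)`.
#' @return an object of class `latent_code` with elements `mu` and `logsig`.
#' @export
latent_code <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  stopifnot(length(mu) == length(sigma))
  structure(list(mu = mu, logsig = log(sigma)), class = "latent_code")
}

#' Posterior standard deviation of a latent code
#' @param code a `latent_code`.
#' @export
code_sigma <- function(code) exp(code$logsig)

#' Encode a window into the variational posterior
#'
#' Deterministic forward map through the (standardized) encoder.
#'
#' @param model an `svae_model`.
#' @param X a C x T window matrix or C x T x B array.
#' @return a [latent_code()]; `mu`/`logsig` are length-L vectors for a
#'   single window and L x B matrices for a batch.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "svae_model"))
  if (!all(is.finite(X))) stop("encoder input must be finite")
  single <- is.matrix(X)
  Xb <- standardize_X(model, as_batch(X, model$n_channels, model$window_len))
  f <- encoder_fwd(model, Xb)
  mu <- f$mu; ls <- f$logsig
  if (single) { mu <- drop(mu); ls <- drop(ls) }
  structure(list(mu = mu, logsig = ls), class = "latent_code")
}

#' Reparameterization: sample the latent code
#'
#' Computes `z = mu + sigma * eps` elementwise.
#'
#' @param code a [latent_code()].
#' @param eps standard-normal draw of the same shape as `code$mu`; drawn
#'   internally when omitted.
#' @return the latent sample z.
#' @export
reparameterize <- function(code, eps = NULL) {
  if (is.null(eps)) eps <- stats::rnorm(length(code$mu))
  if (length(eps) != length(code$mu))
    stop("eps length does not match the latent code")
  code$mu + exp(code$logsig) * eps
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' KL(N(mu, diag sigma^2) || N(0, I)) = 0.5 * sum_l (mu_l^2 + sigma_l^2 -
#' 1 - log sigma_l^2), summed over latent dimensions.
#'
#' @param code a [latent_code()]; if `mu` is an L x B matrix a length-B
#'   vector of per-window divergences is returned.
#' @return non-negative scalar (or vector for a batch).
#' @export
kl_gaussian <- function(code) {
  s2 <- exp(2 * code$logsig)
  term <- 0.5 * (code$mu^2 + s2 - 1 - 2 * code$logsig)
  if (is.matrix(term)) colSums(term) else sum(term)
}

## ---- sine decoder -----------------------------------------------------------

sine_tau <- function(T_len, normalized = FALSE) {
  h <- T_len %/% 2L
  tau <- seq.int(0L, T_len - 1L) - h
  if (normalized) tau / h else as.numeric(tau)
}

# Z: L x B.  Returns Xhat (C x T x B) and cache; the per-window sine
# synthesis runs in compiled code (src/kernels.cpp).
sine_fwd <- function(par, Z, C, H, T_len, tau, prefix = "dec.") {
  vA <- par[[paste0(prefix, "W1")]] %*% Z + par[[paste0(prefix, "b1")]]
  Om <- par[[paste0(prefix, "W2")]] %*% Z + par[[paste0(prefix, "b2")]]
  Ph <- par[[paste0(prefix, "W3")]] %*% Z + par[[paste0(prefix, "b3")]]
  out <- .sine_fwd_cpp(vA, Om, Ph, tau, C)
  list(Xhat = out$Xhat,
       cache = list(vA = vA, Om = Om, Ph = Ph, S = out$S, Z = Z, tau = tau,
                    C = C, H = H))
}

sine_bwd <- function(par, cache, dXhat, prefix = "dec.") {
  out <- .sine_bwd_cpp(cache$vA, cache$Om, cache$Ph, cache$tau, cache$S,
                       dXhat, cache$C)
  dvA <- out$dvA; dOm <- out$dOm; dPh <- out$dPh
  g <- list()
  Zt <- t(cache$Z)
  g[[paste0(prefix, "W1")]] <- dvA %*% Zt
  g[[paste0(prefix, "b1")]] <- rowSums(dvA)
  g[[paste0(prefix, "W2")]] <- dOm %*% Zt
  g[[paste0(prefix, "b2")]] <- rowSums(dOm)
  g[[paste0(prefix, "W3")]] <- dPh %*% Zt
  g[[paste0(prefix, "b3")]] <- rowSums(dPh)
  dZ <- crossprod(par[[paste0(prefix, "W1")]], dvA) +
    crossprod(par[[paste0(prefix, "W2")]], dOm) +
    crossprod(par[[paste0(prefix, "W3")]], dPh)
  list(grads = g, dZ = dZ)
}

#' Standalone sine-decoder parameter set
#'
#' Bundles the three affine maps of the weighted sine-wave decoder for use
#' with [decode_sine()] outside of a full model: amplitudes
#' `A = reshape(W1 z + b1, C x H)`, frequencies `Omega = W2 z + b2`, phases
#' `Phi = W3 z + b3`.
#'
#' @param L latent length; @param C output channels; @param H number of
#'   sine components.
#' @param W1,b1,W2,b2,W3,b3 optional explicit maps (defaults: zero bias,
#'   small random weights).
#' @param tau_normalized see [svae_config()].
#' @param seed optional seed for the random defaults.
#' @return an object of class `sine_decoder_params`.
#' @export
sine_decoder_params <- function(L, C, H, W1 = NULL, b1 = NULL, W2 = NULL,
                                b2 = NULL, W3 = NULL, b3 = NULL,
                                tau_normalized = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list(
    W1 = if (is.null(W1)) glorot(C * H, L) else W1,
    b1 = if (is.null(b1)) numeric(C * H) else b1,
    W2 = if (is.null(W2)) glorot(H, L) * 0.1 else W2,
    b2 = if (is.null(b2)) stats::runif(H, 0.006, 0.3) else b2,
    W3 = if (is.null(W3)) glorot(H, L) * 0.1 else W3,
    b3 = if (is.null(b3)) numeric(H) else b3)
  stopifnot(nrow(p$W1) == C * H, ncol(p$W1) == L, nrow(p$W2) == H,
            nrow(p$W3) == H, length(p$b1) == C * H, length(p$b2) == H,
            length(p$b3) == H)
  structure(c(p, list(L = L, C = C, H = H, tau_normalized = tau_normalized)),
            class = "sine_decoder_params")
}

#' Build sine-decoder parameters that reproduce given sinusoid components
#'
#' Constructs a bias-only parameter set (all weight matrices zero) whose
#' decoding of `z = 0` is exactly `sum_k A[, k] * sin(omega[k] * tau +
#' phi[k])`.
#'
#' @param A C x H0 amplitude matrix; @param omega,phi length-H0 frequency
#'   (rad/sample) and phase vectors.
#' @param L latent length; @param H total components (H0 <= H; the extra
#'   components get zero amplitude).
#' @export
sine_params_from_components <- function(A, omega, phi, L = 2L, H = ncol(A)) {
  C <- nrow(A); H0 <- ncol(A)
  stopifnot(length(omega) == H0, length(phi) == H0, H >= H0)
  b1 <- numeric(C * H); b1[seq_len(C * H0)] <- as.vector(A)
  b2 <- numeric(H); b2[seq_len(H0)] <- omega
  b3 <- numeric(H); b3[seq_len(H0)] <- phi
  sine_decoder_params(L, C, H,
                      W1 = matrix(0, C * H, L), b1 = b1,
                      W2 = matrix(0, H, L), b2 = b2,
                      W3 = matrix(0, H, L), b3 = b3)
}

#' Decode a latent vector with the weighted sine-wave decoder
#'
#' @param z latent vector (length L) or L x B matrix.
#' @param params a [sine_decoder_params()].
#' @param T_len reconstruction length in samples.
#' @return C x T matrix (or C x T x B array for a batch).
#' @export
decode_sine <- function(z, params, T_len) {
  stopifnot(inherits(params, "sine_decoder_params"))
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 1L)
  if (nrow(Z) != params$L) stop("latent length mismatch")
  tau <- sine_tau(T_len, params$tau_normalized)
  par <- list(W1 = params$W1, b1 = params$b1, W2 = params$W2,
              b2 = params$b2, W3 = params$W3, b3 = params$b3)
  names(par) <- paste0("dec.", names(par))
  out <- sine_fwd(par, Z, params$C, params$H, T_len, tau)$Xhat
  if (is.matrix(z)) out else out[, , 1L]
}

## ---- LSTM + transposed-convolution decoder ----------------------------------

lstm_dec_fwd <- function(model, Z) {
  cfg <- model$cfg; par <- model$par
  B <- ncol(Z)
  c_ch <- cfg$conv_channels; T3 <- model$T3
  hin <- tanh(dense_fwd(par[["dec.in.W"]], par[["dec.in.b"]], Z))
  seq_flat <- tanh(dense_fwd(par[["dec.seq.W"]], par[["dec.seq.b"]], hin))
  seed <- array(seq_flat, c(c_ch, T3, B))
  lf <- lstm_fwd(par[["dec.lstm.W"]], par[["dec.lstm.b"]], seed)
  cur <- lf$Y
  tr_caches <- vector("list", cfg$n_conv)
  tr_acts <- vector("list", cfg$n_conv)
  for (i in seq_len(cfg$n_conv)) {
    f <- convtr1d_fwd(par[[paste0("dec.tr", i, ".W")]],
                      par[[paste0("dec.tr", i, ".b")]],
                      cur, cfg$conv_stride, cfg$conv_kernel)
    cur <- if (i < cfg$n_conv) tanh(f$Y) else f$Y
    tr_caches[[i]] <- f$cache
    tr_acts[[i]] <- cur
  }
  list(Xhat = cur,
       cache = list(Z = Z, hin = hin, seq_flat = seq_flat,
                    seed_dim = dim(seed), lstm = lf$cache,
                    tr = tr_caches, tr_acts = tr_acts))
}

lstm_dec_bwd <- function(model, cache, dXhat) {
  cfg <- model$cfg; par <- model$par
  g <- list()
  dcur <- dXhat
  for (i in rev(seq_len(cfg$n_conv))) {
    if (i < cfg$n_conv) dcur <- dcur * (1 - cache$tr_acts[[i]]^2)
    bt <- convtr1d_bwd(par[[paste0("dec.tr", i, ".W")]], cache$tr[[i]], dcur)
    g[[paste0("dec.tr", i, ".W")]] <- bt$dW
    g[[paste0("dec.tr", i, ".b")]] <- bt$db
    dcur <- bt$dX
  }
  bl <- lstm_bwd(par[["dec.lstm.W"]], cache$lstm, dcur)
  g[["dec.lstm.W"]] <- bl$dW; g[["dec.lstm.b"]] <- bl$db
  dseq <- matrix(bl$dX, prod(cache$seed_dim[1:2]), cache$seed_dim[3L])
  dseq <- dseq * (1 - cache$seq_flat^2)
  bs <- dense_bwd(par[["dec.seq.W"]], cache$hin, dseq)
  g[["dec.seq.W"]] <- bs$dW; g[["dec.seq.b"]] <- bs$db
  dhin <- bs$dX * (1 - cache$hin^2)
  bi <- dense_bwd(par[["dec.in.W"]], cache$Z, dhin)
  g[["dec.in.W"]] <- bi$dW; g[["dec.in.b"]] <- bi$db
  list(grads = g, dZ = bi$dX)
}

#' Decode a latent vector with the LSTM/transposed-convolution decoder
#'
#' @param z latent vector or L x B matrix.
#' @param model an `svae_model` built with `decoder = "lstm_cnn"`.
#' @return C x T reconstruction (C x T x B array for a batch).
#' @export
decode_lstm_cnn <- function(z, model) {
  stopifnot(inherits(model, "svae_model"), model$cfg$decoder == "lstm_cnn")
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 1L)
  if (nrow(Z) != model$cfg$latent) stop("latent length mismatch")
  out <- lstm_dec_fwd(model, Z)$Xhat
  if (is.matrix(z)) out else out[, , 1L]
}

## ---- prediction head --------------------------------------------------------

head_fwd <- function(par, Z) {
  h1 <- tanh(dense_fwd(par[["head.h1.W"]], par[["head.h1.b"]], Z))
  yhat <- dense_fwd(par[["head.h2.W"]], par[["head.h2.b"]], h1)
  list(yhat = as.numeric(yhat), cache = list(Z = Z, h1 = h1))
}

head_bwd <- function(par, cache, dyhat) {
  g <- list()
  b2 <- dense_bwd(par[["head.h2.W"]], cache$h1,
                  matrix(dyhat, 1L, length(dyhat)))
  g[["head.h2.W"]] <- b2$dW; g[["head.h2.b"]] <- b2$db
  dh1 <- b2$dX * (1 - cache$h1^2)
  b1 <- dense_bwd(par[["head.h1.W"]], cache$Z, dh1)
  g[["head.h1.W"]] <- b1$dW; g[["head.h1.b"]] <- b1$db
  list(grads = g, dZ = b1$dX)
}

#' Predict speed from a latent vector
#'
#' Runs the prediction head on a latent sample (or posterior mean) and maps
#' the result back to km/h through the model's label normalization.
#'
#' @param model an `svae_model`.
#' @param z latent vector or L x B matrix.
#' @return speed estimate(s) in km/h.
#' @export
predict_speed <- function(model, z) {
  stopifnot(inherits(model, "svae_model"))
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 1L)
  if (!all(is.finite(Z))) stop("latent input must be finite")
  yh <- head_fwd(model$par, Z)$yhat
  yh <- yh * model$norm$y_sd + model$norm$y_mean
  if (is.matrix(z)) yh else yh[1L]
}

#' Predict speeds for a window set
#'
#' Deterministic prediction using the posterior mean (`z = mu`).
#'
#' @param object a trained `svae_model`.
#' @param ws a [window_set()].
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return numeric vector of speeds (km/h), one per window.
#' @export
predict.svae_model <- function(object, ws, batch_size = 256L, ...) {
  stopifnot(inherits(ws, "window_set"))
  N <- n_windows(ws)
  out <- numeric(N)
  for (at in seq.int(1L, N, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, N)
    Xb <- standardize_X(object, ws$X[, , idx, drop = FALSE])
    f <- encoder_fwd(object, Xb)
    out[idx] <- head_fwd(object$par, f$mu)$yhat
  }
  out <- out * object$norm$y_sd + object$norm$y_mean
  if (!is.null(object$norm$y_range))
    out <- pmin(pmax(out, object$norm$y_range[1L]), object$norm$y_range[2L])
  out
}

## ---- losses -----------------------------------------------------------------

#' Feed-forward (supervised) loss
#'
#' Squared L2 error between measured and predicted speeds.
#'
#' @param y,yhat numeric vectors of equal length (km/h).
#' @return non-negative scalar `sum((y - yhat)^2)`.
#' @export
feedforward_loss <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  sum((y - yhat)^2)
}

#' Autoencoder reconstruction loss
#'
#' Mean squared error over the window elements (see the package vignette
#' for the scaling convention).
#'
#' @param X,Xhat window and reconstruction of identical shape.
#' @return non-negative scalar.
#' @export
autoencoder_loss <- function(X, Xhat) {
  stopifnot(all(dim(X) == dim(Xhat)))
  mean((X - Xhat)^2)
}

#' Semi-supervised VAE loss
#'
#' `alpha * (y - yhat)^2 + mean((X - Xhat)^2) + beta * KL(q || N(0, I))`,
#' where `yhat` and `Xhat` must be computed from one shared
#' reparameterization draw.  The three addends are returned individually
#' alongside the total.
#'
#' @param X window; @param y label (km/h).
#' @param Xhat reconstruction; @param yhat predicted speed.
#' @param code the [latent_code()] of the window.
#' @param alpha prediction weight (>= 0); @param beta KL weight (>= 0).
#' @return list with `total`, `prediction`, `reconstruction`, `kl`.
#' @export
svae_loss <- function(X, y, Xhat, yhat, code, alpha, beta) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  pred <- (y - yhat)^2
  recon <- autoencoder_loss(X, Xhat)
  kl <- kl_gaussian(code)
  list(total = alpha * pred + recon + beta * kl,
       prediction = pred, reconstruction = recon, kl = kl)
}

## ---- joint batch forward / backward (training core) ------------------------

# X: standardized C x T x B, y: standardized length-B, eps: L x B.
svae_batch_fwd <- function(model, X, y, eps, alpha, beta) {
  enc <- encoder_fwd(model, X)
  sig <- exp(enc$logsig)
  Z <- enc$mu + sig * eps
  hd <- head_fwd(model$par, Z)
  if (model$cfg$decoder == "sine") {
    tau <- sine_tau(model$window_len, model$cfg$tau_normalized)
    dec <- sine_fwd(model$par, Z, model$n_channels,
                    model$cfg$sine_components, model$window_len, tau)
  } else {
    dec <- lstm_dec_fwd(model, Z)
  }
  B <- dim(X)[3L]
  n_el <- prod(dim(X)[1:2])
  pred <- mean((y - hd$yhat)^2)
  recon <- sum((X - dec$Xhat)^2) / (n_el * B)
  kl_each <- 0.5 * colSums(enc$mu^2 + sig^2 - 1 - 2 * enc$logsig)
  kl <- mean(kl_each)
  list(total = alpha * pred + recon + beta * kl,
       prediction = pred, reconstruction = recon, kl = kl,
       enc = enc, sig = sig, Z = Z, head = hd, dec = dec, eps = eps)
}

svae_batch_bwd <- function(model, X, y, fw, alpha, beta) {
  B <- dim(X)[3L]
  n_el <- prod(dim(X)[1:2])
  dyhat <- alpha * 2 * (fw$head$yhat - y) / B
  dXhat <- 2 * (fw$dec$Xhat - X) / (n_el * B)
  hb <- head_bwd(model$par, fw$head$cache, dyhat)
  if (model$cfg$decoder == "sine") {
    db <- sine_bwd(model$par, fw$dec$cache, dXhat)
  } else {
    db <- lstm_dec_bwd(model, fw$dec$cache, dXhat)
  }
  dZ <- hb$dZ + db$dZ
  dmu <- dZ + (beta / B) * fw$enc$mu
  dls <- dZ * fw$eps * fw$sig + (beta / B) * (fw$sig^2 - 1)
  eb <- encoder_bwd(model, fw$enc$cache, dmu, dls)
  c(eb$grads, hb$grads, db$grads)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full parameter set, architecture
#' configuration and normalization record.
#'
#' @param model an `svae_model`; @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "svae_model"))
  model
}
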