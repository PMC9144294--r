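# Monte-Carlo KL oracle, independent of the closed form
mc_kl <- function(mu, sigma, n = 1e5, seed = 1L) {
  set.seed(seed)
  L <- length(mu)
  eps <- matrix(rnorm(L * n), L)
  z <- mu + sigma * eps
  lq <- colSums(dnorm(z, mu, sigma, log = TRUE))
  lp <- colSums(dnorm(z, 0, 1, log = TRUE))
  mean(lq - lp)
}

test_that("closed-form KL matches hand values and the Monte-Carlo oracle", {
  expect_equal(kl_gaussian(latent_code(rep(0, 4), rep(1, 4))), 0)
  expect_equal(kl_gaussian(latent_code(1, 1)), 0.5)
  set.seed(10)
  for (i in 1:5) {
    mu <- runif(4, -2, 2)
    sigma <- runif(4, 0.5, 2)
    cf <- kl_gaussian(latent_code(mu, sigma))
    expect_gte(cf, 0)
    expect_lt(abs(cf - mc_kl(mu, sigma, n = 2e5, seed = i)) / cf, 0.01)
  }
  expect_error(latent_code(c(0, 0), c(1, 0)), "strictly positive")
})

test_that("reparameterization is mu + sigma * eps with matching moments", {
  code <- latent_code(c(1, -2, 0.5), c(0.5, 1, 2))
  expect_equal(reparameterize(code, c(0, 0, 0)), code$mu)
  expect_equal(reparameterize(code, c(1, 1, 1)), code$mu + code_sigma(code))
  expect_error(reparameterize(code, c(0, 0)), "length")
  # degenerate posterior: sigma -> 0 collapses onto mu for any eps
  tiny <- latent_code(c(3, -1), c(1e-300, 1e-300))
  expect_equal(reparameterize(tiny, c(5, -9)), tiny$mu)
  set.seed(11)
  draws <- replicate(1e5, reparameterize(code))
  expect_lt(max(abs(rowMeans(draws) - code$mu)), 0.02 * max(abs(code$mu)))
  expect_lt(max(abs(apply(draws, 1, sd) - code_sigma(code)) /
                code_sigma(code)), 0.02)
})

test_that("the encoder is a deterministic map with positive sigma", {
  cfg <- svae_config(conv_channels = 2L, hidden_size = 16L, latent = 8L,
                     n_conv = 2L)
  set.seed(12)
  for (trial in 1:10) {
    model <- svae_init(3L, 64L, cfg)
    X <- matrix(rnorm(3 * 64, sd = runif(1, 0.1, 10)), 3L)
    code <- encode(model, X)
    expect_length(code$mu, 8L)
    expect_length(code$logsig, 8L)
    expect_true(all(code_sigma(code) > 0))
    code2 <- encode(model, X)
    expect_identical(code$mu, code2$mu)
    expect_identical(code$logsig, code2$logsig)
  }
  model <- svae_init(3L, 64L, cfg, seed = 1L)
  X <- matrix(rnorm(3 * 64), 3L)
  X[1, 1] <- NA
  expect_error(encode(model, X), "finite")
})

test_that("the sine decoder reproduces explicit sinusoid sums exactly", {
  T_len <- 128L
  tau <- seq.int(0L, T_len - 1L) - 64L
  A <- rbind(c(2, 0.5, 1), c(-1, 3, 0.2))
  omega <- c(0.05, 0.21, 0.4)
  phi <- c(0.3, -1, 2)
  target <- matrix(0, 2L, T_len)
  for (k in 1:3)
    target <- target + A[, k] %o% sin(omega[k] * tau + phi[k])
  # H0 = 3 components embedded in an H = 10 decoder, extra amplitudes zero
  params <- sine_params_from_components(A, omega, phi, L = 4L, H = 10L)
  xhat <- decode_sine(rep(0, 4), params, T_len)
  expect_lt(mean((xhat - target)^2), 1e-10)
  # zero latent with bias-free maps decodes to silence
  p0 <- sine_decoder_params(4L, 2L, 5L,
                            W1 = matrix(0.7, 10L, 4L), b1 = rep(0, 10L),
                            W2 = matrix(0.3, 5L, 4L), b2 = rep(0, 5L),
                            W3 = matrix(-0.2, 5L, 4L), b3 = rep(0, 5L))
  expect_equal(decode_sine(rep(0, 4), p0, 32L), matrix(0, 2L, 32L))
})

test_that("sine reconstructions are bounded by the total amplitude", {
  set.seed(13)
  params <- sine_decoder_params(L = 3L, C = 2L, H = 6L, seed = 14L)
  for (i in 1:20) {
    z <- rnorm(3)
    xhat <- decode_sine(z, params, 64L)
    A <- matrix(params$W1 %*% z + params$b1, 2L, 6L)
    expect_true(all(abs(xhat) <= rowSums(abs(A)) + 1e-12))
  }
})

test_that("sine-decoder gradients match central finite differences", {
  set.seed(15)
  C <- 2L; T_len <- 32L; L <- 3L; H <- 4L
  par <- list(dec.W1 = matrix(rnorm(C * H * L, sd = 0.5), C * H, L),
              dec.b1 = rnorm(C * H, sd = 0.2),
              dec.W2 = matrix(rnorm(H * L, sd = 0.1), H, L),
              dec.b2 = runif(H, 0.05, 0.5),
              dec.W3 = matrix(rnorm(H * L, sd = 0.1), H, L),
              dec.b3 = rnorm(H, sd = 0.2))
  tau <- gaitspeed:::sine_tau(T_len)
  Z <- matrix(rnorm(L * 2L), L)
  target <- array(rnorm(C * T_len * 2L), c(C, T_len, 2L))
  loss_of <- function(p) {
    f <- gaitspeed:::sine_fwd(p, Z, C, H, T_len, tau)
    mean((f$Xhat - target)^2)
  }
  f <- gaitspeed:::sine_fwd(par, Z, C, H, T_len, tau)
  dXhat <- 2 * (f$Xhat - target) / length(target)
  analytic <- gaitspeed:::sine_bwd(par, f$cache, dXhat)$grads
  eps <- 1e-6
  for (nm in names(par)) {
    for (e in seq_len(min(length(par[[nm]]), 8L))) {
      pp <- par; pp[[nm]][e] <- pp[[nm]][e] + eps
      pm <- par; pm[[nm]][e] <- pm[[nm]][e] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_lt(abs(analytic[[nm]][e] - num) / max(abs(num), 1e-8), 1e-4)
    }
  }
})

test_that("the LSTM-deconvolution decoder meets its shape contract", {
  for (hc in list(c(2L, 128L), c(8L, 256L))) {
    cfg <- svae_config(conv_channels = hc[1L], hidden_size = hc[2L],
                       latent = 64L, decoder = "lstm_cnn", n_conv = 2L)
    model <- svae_init(5L, 96L, cfg, seed = 16L)
    z <- rnorm(64)
    xhat <- decode_lstm_cnn(z, model)
    expect_equal(dim(xhat), c(5L, 96L))
    expect_identical(xhat, decode_lstm_cnn(z, model))
  }
})

test_that("the LSTM-deconvolution decoder can fit a few fixed windows", {
  set.seed(17)
  cfg <- svae_config(conv_channels = 8L, hidden_size = 32L, latent = 6L,
                     decoder = "lstm_cnn", n_conv = 2L)
  model <- svae_init(1L, 64L, cfg, seed = 18L)
  tt <- seq_len(64L)
  X <- array(0, c(1L, 64L, 4L))
  for (k in 1:4) X[1, , k] <- sin(2 * pi * k * tt / 64) * 0.8
  Z <- matrix(rnorm(6L * 4L), 6L)
  dec_par <- grep("^dec\\.", names(model$par), value = TRUE)
  state <- gaitspeed:::adam_init(model$par[dec_par])
  mse <- Inf
  for (it in 1:600) {
    f <- gaitspeed:::lstm_dec_fwd(model, Z)
    mse <- mean((f$Xhat - X)^2)
    if (mse < 1e-2) break
    g <- gaitspeed:::lstm_dec_bwd(model, f$cache,
                                  2 * (f$Xhat - X) / length(X))$grads
    upd <- gaitspeed:::adam_step(model$par[dec_par], g[dec_par], state,
                                 lr = 5e-3)
    model$par[dec_par] <- upd$par
    state <- upd$state
  }
  expect_lt(mse, 1e-2)
})

test_that("the prediction head is deterministic and recovers linear maps", {
  cfg <- svae_config(conv_channels = 2L, latent = 4L, head_hidden = 8L,
                     n_conv = 2L)
  model <- svae_init(2L, 32L, cfg, seed = 19L)
  z <- rnorm(4)
  expect_identical(predict_speed(model, z), predict_speed(model, z))
  zero <- model
  zero$par[["head.h1.W"]][] <- 0; zero$par[["head.h1.b"]][] <- 0
  zero$par[["head.h2.W"]][] <- 0; zero$par[["head.h2.b"]][] <- 0
  expect_equal(predict_speed(zero, z), 0)

  # train the head alone on y linear in z
  set.seed(20)
  Z <- matrix(rnorm(4 * 200), 4L)
  w_true <- c(0.5, -1, 0.25, 2)
  y <- drop(crossprod(Z, w_true))
  head_par <- grep("^head\\.", names(model$par), value = TRUE)
  state <- gaitspeed:::adam_init(model$par[head_par])
  for (it in 1:2500) {
    hf <- gaitspeed:::head_fwd(model$par, Z)
    hb <- gaitspeed:::head_bwd(model$par, hf$cache,
                               2 * (hf$yhat - y) / length(y))
    upd <- gaitspeed:::adam_step(model$par[head_par], hb$grads[head_par],
                                 state, lr = 1e-2)
    model$par[head_par] <- upd$par
    state <- upd$state
  }
  expect_lt(mean((gaitspeed:::head_fwd(model$par, Z)$yhat - y)^2), 1e-3)
})

test_that("the feed-forward loss is the squared error", {
  expect_equal(feedforward_loss(5, 3), 4)
  expect_equal(feedforward_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(feedforward_loss(c(1, 2), c(3, 0)), feedforward_loss(c(3, 0), c(1, 2)))
})

test_that("the joint loss decomposes into its three documented terms", {
  # fully hand-computed toy instance: C = 1, T = 4, L = 2
  X <- matrix(c(1, 2, 3, 4), 1L)
  Xhat <- matrix(c(1, 1, 2, 5), 1L)
  code <- latent_code(c(0.5, -1), c(1, 0.5))
  out <- svae_loss(X, y = 5, Xhat, yhat = 3.5, code,
                   alpha = 0.1, beta = 0.01)
  expect_equal(out$prediction, 2.25)
  expect_equal(out$reconstruction, (0 + 1 + 1 + 1) / 4)
  expect_equal(out$kl, 0.25 + log(2))
  expect_equal(out$total, 0.1 * 2.25 + 0.75 + 0.01 * (0.25 + log(2)),
               tolerance = 1e-9)
  expect_gte(out$total, 0)
  # limiting cases
  expect_equal(svae_loss(X, 5, Xhat, 3.5, code, 0, 0)$total,
               autoencoder_loss(X, Xhat), tolerance = 1e-12)
  expect_equal(svae_loss(X, 5, Xhat, 3.5, code, 0.3, 0)$total,
               autoencoder_loss(X, Xhat) + 0.3 * 2.25, tolerance = 1e-12)
  expect_error(svae_loss(X, 5, Xhat, 3.5, code, -0.1, 0), "non-negative")
})

test_that("the training loss assembles the same numbers as svae_loss", {
  # one shared reparameterization draw feeds both prediction and
  # reconstruction; the batched training forward must agree with the
  # step-by-step public API on a fresh (identity-normalization) model
  cfg <- svae_config(conv_channels = 2L, hidden_size = 8L, latent = 3L,
                     decoder = "sine", sine_components = 4L, n_conv = 2L)
  model <- svae_init(2L, 32L, cfg, seed = 21L)
  set.seed(22)
  X <- matrix(rnorm(2 * 32), 2L)
  y <- 4.2
  eps <- rnorm(3)
  code <- encode(model, X)
  z <- reparameterize(code, eps)
  yhat <- predict_speed(model, z)
  params <- sine_decoder_params(3L, 2L, 4L,
                                W1 = model$par$dec.W1, b1 = model$par$dec.b1,
                                W2 = model$par$dec.W2, b2 = model$par$dec.b2,
                                W3 = model$par$dec.W3, b3 = model$par$dec.b3)
  xhat <- decode_sine(z, params, 32L)
  manual <- svae_loss(X, y, xhat, yhat, code, alpha = 0.05, beta = 1e-3)
  fw <- gaitspeed:::svae_batch_fwd(model, array(X, c(2, 32, 1)), y,
                                   matrix(eps, ncol = 1), 0.05, 1e-3)
  expect_equal(fw$total, manual$total, tolerance = 1e-9)
  expect_equal(fw$prediction, manual$prediction, tolerance = 1e-9)
  expect_equal(fw$reconstruction, manual$reconstruction, tolerance = 1e-9)
  expect_equal(fw$kl, manual$kl, tolerance = 1e-9)
})

test_that("model checkpoints round-trip with their hyper-parameter record", {
  model <- svae_init(2L, 32L, svae_config(conv_channels = 2L, latent = 4L,
                                          n_conv = 2L), seed = 23L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$par, model$par)
  expect_identical(back$cfg, model$cfg)
  expect_identical(back$norm, model$norm)
})
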