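# Shared fixture builders.  Everything is generated in code at test time.

# minimal valid 20-column raw-count matrix
toy_raw_matrix <- function(n = 3L, seed = 1L) {
  set.seed(seed)
  mat <- matrix(round(rnorm(n * 18L, 0, 100)), n, 18L)
  cbind(mat, seq_len(n) * 0.5, (seq_len(n) - 1L) / 400)
}

toy_recording <- function(n = 3L, seed = 1L, subject_id = "T1") {
  raw_recording(toy_raw_matrix(n, seed), subject_id)
}

# small unit-converted synthetic recording (fast to build)
small_synth_recording <- function(seed = 1L, duration = 30,
                                  speed = NULL) {
  params <- gait_model_params(seed = seed)
  profile <- if (is.null(speed))
    generate_speed_profile(duration, seed = seed + 7L)
  else
    constant_speed_profile(speed, duration)
  synthesize_recording(params, profile, seed = seed + 13L,
                       subject_id = paste0("S", seed))
}

# a tiny cohort of per-subject window sets (cheap: short recordings,
# foot sensor, non-overlapping windows)
tiny_cohort_windows <- function(n_subjects = 3L, duration = 30,
                                stride = 1024L, placements = "foot",
                                seed = 1L) {
  recs <- simulate_cohort(n_subjects, duration = duration, seed = seed)
  lapply(recs, prepare_windows, placements = placements, stride = stride)
}

# small trainable window set with a direct speed -> amplitude relation
toy_window_set <- function(N = 40L, C = 2L, T_len = 64L, seed = 1L,
                           subject = "A") {
  set.seed(seed)
  X <- array(0, c(C, T_len, N))
  dimnames(X) <- list(paste0("foot_", c("acc", "gyr"), "_x")[seq_len(C)],
                      NULL, NULL)
  y <- runif(N, 1, 10)
  tt <- seq_len(T_len)
  for (k in seq_len(N))
    for (c_i in seq_len(C))
      X[c_i, , k] <- y[k] * sin(2 * pi * 0.05 * c_i * tt + c_i) +
        rnorm(T_len, 0, 0.05)
  window_set(X, y, rep(subject, N), rate = 32)
}

toy_hp <- function(..., seed = 1L) {
  hyper_params(svae_config(conv_channels = 2L, hidden_size = 16L,
                           hidden_depth = 1L, latent = 8L,
                           decoder = "sine", sine_components = 4L,
                           n_conv = 2L, head_hidden = 8L),
               alpha = 0.1, beta = 1e-5, lr = 5e-3, batch_size = 16L,
               seed = seed, ...)
}
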