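# Training with early stopping, uniform random hyper-parameter search,
# subject-wise leave-one-out cross-validation, the two-level MAE metric and
# the sensor-combination study.

#' Split a window set into training and validation parts
#'
#' The validation part is taken as one contiguous block of windows per
#' subject (random block position), never a random scatter: neighbouring
#' windows overlap when the stride is below the window length, and a random
#' scatter would leak nearly identical windows between the two parts.
#'
#' @param ws a [window_set()].
#' @param frac training fraction (default 0.85).
#' @param seed optional integer seed; the same seed reproduces the split.
#' @return list with elements `train` and `val` (disjoint window sets whose
#'   union is `ws`).
#' @export
split_train_val <- function(ws, frac = 0.85, seed = NULL) {
  stopifnot(inherits(ws, "window_set"), frac > 0, frac < 1)
  N <- n_windows(ws)
  if (N < 2L) stop("need at least 2 windows to split")
  if (!is.null(seed)) set.seed(seed)
  val_idx <- integer(0)
  for (s in unique(ws$subject)) {
    idx <- which(ws$subject == s)
    n_val <- max(1L, round((1 - frac) * length(idx)))
    if (n_val >= length(idx)) n_val <- length(idx) - 1L
    start <- sample.int(length(idx) - n_val + 1L, 1L)
    val_idx <- c(val_idx, idx[start + seq_len(n_val) - 1L])
  }
  list(train = ws_subset(ws, setdiff(seq_len(N), val_idx)),
       val = ws_subset(ws, sort(val_idx)))
}

#' Scan a validation-error sequence for the early-stopping point
#'
#' Training stops once the metric has not improved (strictly decreased
#' below the running best) for `patience` consecutive checks.  This is the
#' exact rule used inside [train_model()], exposed so that the stopping
#' behaviour can be audited on a recorded history.
#'
#' @param values numeric vector of validation metrics, one per check.
#' @param patience number of consecutive non-improving checks tolerated.
#' @return list with `stop_index` (the check at which training stops, `NA`
#'   if the sequence ends first), `best_index` and `best` value.
#' @export
early_stop_scan <- function(values, patience = 20L) {
  best <- Inf; best_i <- NA_integer_; wait <- 0L
  for (i in seq_along(values)) {
    if (values[i] < best) {
      best <- values[i]; best_i <- i; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience)
        return(list(stop_index = i, best_index = best_i, best = best))
    }
  }
  list(stop_index = NA_integer_, best_index = best_i, best = best)
}

#' Hyper-parameter bundle
#'
#' @param cfg an [svae_config()].
#' @param alpha prediction weight; @param beta KL weight.
#' @param lr Adam learning rate; @param batch_size mini-batch size.
#' @param max_epochs training epoch cap.
#' @param clip_norm global gradient-norm clipping threshold (the
#'   sine-decoder frequency gradients scale with the window offset and can
#'   spike; clipping keeps the optimization stable).  `Inf` disables.
#' @param input_scale standardized channels are divided by this factor
#'   before entering the encoder.  Values > 1 keep even high-amplitude
#'   (fast-running) windows inside the linear zone of the tanh units, so
#'   amplitude differences remain visible to the network instead of being
#'   compressed by activation saturation; 3 maps +-3 sd into +-1.
#' @param weight_decay decoupled L2 weight decay applied after each Adam
#'   step (weight matrices only, not biases); limits memorization of
#'   subject fingerprints in small cohorts.  0 disables.
#' @param seed integer seed controlling initialization, shuffling and the
#'   reparameterization draws.
#' @return an object of class `hyper_params`.
#' @export
hyper_params <- function(cfg = svae_config(), alpha = 0.01, beta = 1e-5,
                         lr = 1e-3, batch_size = 64L, max_epochs = 100L,
                         clip_norm = 100, input_scale = 1,
                         weight_decay = 0, seed = 1L) {
  stopifnot(inherits(cfg, "svae_config"), alpha >= 0, beta >= 0, lr > 0,
            clip_norm > 0, input_scale > 0, weight_decay >= 0)
  structure(list(cfg = cfg, alpha = alpha, beta = beta, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 clip_norm = clip_norm, input_scale = input_scale,
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "hyper_params")
}

#' Train an SVAE with early stopping
#'
#' Runs mini-batch Adam on the joint loss, evaluates the validation MSE of
#' the speed prediction once per epoch, stops when it has not improved for
#' `patience` consecutive evaluations, and restores the weights of the best
#' validation epoch.  Input channels and labels are standardized using
#' training-set statistics stored in the returned model.
#'
#' @param train,val [window_set()]s; both must be non-empty.
#' @param hp a [hyper_params()].
#' @param patience early-stopping patience (default 20 checks).
#' @param validation_metric optional numeric vector overriding the computed
#'   per-epoch validation metric (for auditing the stopping rule); entries
#'   are consumed one per epoch.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-validation weights), `history`
#'   (data.frame of per-epoch loss terms and validation metric),
#'   `best_epoch`, `stopped_epoch`.
#' @export
train_model <- function(train, val, hp, patience = 20L,
                        validation_metric = NULL, verbose = FALSE) {
  stopifnot(inherits(train, "window_set"), inherits(val, "window_set"),
            inherits(hp, "hyper_params"))
  if (n_windows(train) == 0L || n_windows(val) == 0L)
    stop("train and validation sets must be non-empty")
  set.seed(hp$seed)
  C <- dim(train$X)[1L]; T_len <- dim(train$X)[2L]
  model <- svae_init(C, T_len, hp$cfg)
  model$norm <- list(
    ch_mean = apply(train$X, 1L, mean),
    ch_sd = pmax(apply(train$X, 1L, stats::sd), 1e-8) * hp$input_scale,
    y_mean = mean(train$y),
    y_sd = max(stats::sd(train$y), 1e-8),
    # speed is bounded; clamping predictions to the observed label range
    # guards against extrapolation on out-of-cohort subjects
    y_range = c(max(min(train$y), 0), max(train$y)))
  Xs <- standardize_X(model, train$X)
  ys <- (train$y - model$norm$y_mean) / model$norm$y_sd
  state <- adam_init(model$par)
  L <- hp$cfg$latent
  N <- n_windows(train)
  bs <- min(hp$batch_size, N)
  best <- Inf; best_par <- model$par; best_epoch <- 0L; wait <- 0L
  hist <- list()
  epoch <- 0L
  while (epoch < hp$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(N)
    tots <- preds <- recs <- kls <- 0; nb <- 0L
    for (at in seq.int(1L, N, by = bs)) {
      idx <- ord[at:min(at + bs - 1L, N)]
      Xb <- Xs[, , idx, drop = FALSE]
      yb <- ys[idx]
      eps <- matrix(stats::rnorm(L * length(idx)), L)
      fw <- svae_batch_fwd(model, Xb, yb, eps, hp$alpha, hp$beta)
      if (!is.finite(fw$total))
        stop(sprintf(
          "training diverged at epoch %d (loss %g, recon %g, kl %g)",
          epoch, fw$total, fw$reconstruction, fw$kl))
      grads <- svae_batch_bwd(model, Xb, yb, fw, hp$alpha, hp$beta)
      if (is.finite(hp$clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
        if (gn > hp$clip_norm) {
          sc <- hp$clip_norm / gn
          grads <- lapply(grads, `*`, sc)
        }
      }
      upd <- adam_step(model$par, grads, state, lr = hp$lr)
      model$par <- upd$par; state <- upd$state
      if (hp$weight_decay > 0) {
        wd <- 1 - hp$lr * hp$weight_decay
        wnames <- grep("\\.W[0-9]?$", names(model$par), value = TRUE)
        for (nm in wnames) model$par[[nm]] <- model$par[[nm]] * wd
      }
      tots <- tots + fw$total; preds <- preds + fw$prediction
      recs <- recs + fw$reconstruction; kls <- kls + fw$kl
      nb <- nb + 1L
    }
    vm <- if (!is.null(validation_metric)) {
      if (epoch > length(validation_metric))
        stop("validation_metric override exhausted")
      validation_metric[epoch]
    } else {
      mean((predict(model, val) - val$y)^2)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tots / nb,
                                prediction = preds / nb,
                                reconstruction = recs / nb, kl = kls / nb,
                                val_metric = vm)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  pred %.5f  recon %.5f  val %.5f",
                      epoch, tots / nb, preds / nb, recs / nb, vm))
    if (vm < best) {
      best <- vm; best_par <- model$par; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$par <- best_par
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best_epoch, stopped_epoch = epoch)
}

#' Hyper-parameter search space
#'
#' The grids over which [random_search()] draws uniformly: encoder
#' convolution channels {1, 2, 4, 8, 16}, hidden size {128, 256, 512},
#' hidden depth {1, 2}, latent length {64, 128, 256}, prediction weight
#' alpha {1e-1, 1e-2, 1e-3, 1e-4}, KL weight beta {1e-4 ... 1e-7} and, for
#' the sine decoder, H in {10, 50, 100}.
#'
#' @return named list of grids.
#' @export
svae_search_space <- function() {
  list(conv_channels = c(1L, 2L, 4L, 8L, 16L),
       hidden_size = c(128L, 256L, 512L),
       hidden_depth = c(1L, 2L),
       latent = c(64L, 128L, 256L),
       alpha = c(1e-1, 1e-2, 1e-3, 1e-4),
       beta = c(1e-4, 1e-5, 1e-6, 1e-7),
       sine_components = c(10L, 50L, 100L))
}

#' Uniform random hyper-parameter search draws
#'
#' Each draw selects one value uniformly and independently from every grid.
#'
#' @param n_draws number of configurations to draw (default 15).
#' @param decoder decoder family the draws are for.
#' @param space list of grids (default [svae_search_space()]).
#' @param seed optional integer seed.
#' @param ... forwarded to [hyper_params()] (e.g. `max_epochs`).
#' @return list of `n_draws` [hyper_params()] objects.
#' @export
random_search <- function(n_draws = 15L, decoder = c("sine", "lstm_cnn"),
                          space = svae_search_space(), seed = NULL, ...) {
  decoder <- match.arg(decoder)
  stopifnot(all(lengths(space) > 0L))
  if (!is.null(seed)) set.seed(seed)
  draw1 <- function(g) g[sample.int(length(g), 1L)]
  lapply(seq_len(n_draws), function(i) {
    cfg <- svae_config(
      conv_channels = draw1(space$conv_channels),
      hidden_size = draw1(space$hidden_size),
      hidden_depth = draw1(space$hidden_depth),
      latent = draw1(space$latent),
      decoder = decoder,
      sine_components = if (decoder == "sine")
        draw1(space$sine_components) else 10L)
    hyper_params(cfg, alpha = draw1(space$alpha), beta = draw1(space$beta),
                 seed = sample.int(.Machine$integer.max, 1L), ...)
  })
}

#' Two-level mean absolute error
#'
#' The evaluation metric: for each subject the mean over time of
#' |y - yhat|, averaged over subjects with equal weight.
#'
#' @param truths,preds named lists of per-subject numeric vectors (km/h),
#'   aligned elementwise.
#' @return scalar error in km/h.
#' @export
mean_absolute_error <- function(truths, preds) {
  stopifnot(length(truths) >= 1L, length(truths) == length(preds))
  per <- mapply(function(y, yh) {
    if (length(y) != length(yh)) stop("prediction/truth length mismatch")
    mean(abs(y - yh))
  }, truths, preds)
  mean(per)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the subject's windows are held out entirely, the
#' remaining subjects are split 85/15 into training and validation (block
#' split per subject), the training part is optionally augmented, a model
#' is trained with early stopping, and the held-out subject is predicted
#' once.
#'
#' @param subject_ws named list of per-subject [window_set()]s (>= 2
#'   subjects).
#' @param hp a [hyper_params()].
#' @param patience early-stopping patience.
#' @param augment optional [augment_config()] applied to the training part
#'   of each fold only.
#' @param frac training fraction of the 85/15 split.
#' @param seed integer seed from which per-fold seeds are derived.
#' @param checkpoint_dir optional directory; when given, each fold's
#'   trained model is saved there as `fold_<subject>.rds`.
#' @param verbose print per-fold progress.
#' @return an object of class `cv_result`: list with `per_subject_mae`
#'   (named, km/h), `mean_mae`, `folds` (per-fold predictions, truths,
#'   subject composition and history) and `hp`.
#' @export
loocv <- function(subject_ws, hp, patience = 20L, augment = NULL,
                  frac = 0.85, seed = 1L, checkpoint_dir = NULL,
                  verbose = FALSE) {
  stopifnot(is.list(subject_ws), length(subject_ws) >= 2L)
  subjects <- names(subject_ws)
  if (is.null(subjects))
    subjects <- vapply(subject_ws, function(w) w$subject[1L], character(1))
  folds <- vector("list", length(subjects))
  per_mae <- stats::setNames(numeric(length(subjects)), subjects)
  for (i in seq_along(subjects)) {
    test_subj <- subjects[i]
    pool <- ws_concat(subject_ws[-i])
    sp <- split_train_val(pool, frac = frac, seed = seed + 1000L * i)
    train <- sp$train
    if (!is.null(augment)) {
      augment$seed <- seed + 1000L * i + 1L
      train <- augment_batch(train, augment)
    }
    hp_fold <- hp
    hp_fold$seed <- hp$seed + i
    fit <- train_model(train, sp$val, hp_fold, patience = patience)
    if (!is.null(checkpoint_dir)) {
      if (!dir.exists(checkpoint_dir))
        dir.create(checkpoint_dir, recursive = TRUE)
      save_model(fit$model,
                 file.path(checkpoint_dir, paste0("fold_", test_subj, ".rds")))
    }
    test_ws <- subject_ws[[i]]
    preds <- predict(fit$model, test_ws)
    per_mae[test_subj] <- mean(abs(preds - test_ws$y))
    folds[[i]] <- list(test_subject = test_subj,
                       train_subjects = unique(train$subject),
                       val_subjects = unique(sp$val$subject),
                       n_train = n_windows(train), n_val = n_windows(sp$val),
                       predictions = preds, truths = test_ws$y,
                       best_epoch = fit$best_epoch,
                       stopped_epoch = fit$stopped_epoch,
                       history = fit$history)
    if (verbose)
      message(sprintf("fold %s: MAE %.3f km/h (stopped %d, best %d)",
                      test_subj, per_mae[test_subj], fit$stopped_epoch,
                      fit$best_epoch))
  }
  structure(list(per_subject_mae = per_mae, mean_mae = mean(per_mae),
                 folds = folds, hp = hp),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d subjects, mean MAE %.3f km/h\n",
              length(x$per_subject_mae), x$mean_mae))
  print(round(x$per_subject_mae, 3))
  invisible(x)
}

#' Constant-mean baseline error under the same LOOCV protocol
#'
#' For each fold the predictor is the mean training speed; reported with
#' the same two-level MAE as [loocv()].  This is the sanity floor any
#' learning method must beat.
#'
#' @param subject_ws named list of per-subject window sets.
#' @return list with `per_subject_mae` and `mean_mae` (km/h).
#' @export
constant_predictor_mae <- function(subject_ws) {
  subjects <- names(subject_ws)
  per <- stats::setNames(numeric(length(subjects)), subjects)
  for (i in seq_along(subjects)) {
    train_y <- unlist(lapply(subject_ws[-i], `[[`, "y"))
    per[i] <- mean(abs(subject_ws[[i]]$y - mean(train_y)))
  }
  list(per_subject_mae = per, mean_mae = mean(per))
}

all_placement_subsets <- function() {
  subs <- list()
  for (k in 1:3)
    subs <- c(subs, utils::combn(SENSOR_PLACEMENTS, k, simplify = FALSE))
  subs
}

#' Sensor-placement combination study
#'
#' Runs the LOOCV evaluation for every requested subset of sensor
#' placements (by default all 7 non-empty subsets of thigh/shin/foot),
#' re-using one hyper-parameter bundle across subsets.
#'
#' @param subject_urecs named list of per-subject `uniform_recording`s
#'   containing all three placements.
#' @param hp a [hyper_params()] shared by all subsets.
#' @param subsets list of placement character vectors (default all 7).
#' @param stride window stride in samples (default window length / 2).
#' @param window_s window length in seconds.
#' @param ... forwarded to [loocv()].
#' @return data.frame with one row per subset: `placements`, `n_channels`,
#'   `mean_mae` plus the per-subject errors as a list column `per_subject`.
#' @export
sensor_combination_study <- function(subject_urecs, hp,
                                     subsets = all_placement_subsets(),
                                     stride = NULL, window_s = 2, ...) {
  have <- rownames(subject_urecs[[1L]]$signal)
  for (p in SENSOR_PLACEMENTS)
    if (!all(channel_names(p) %in% have))
      stop("placement '", p, "' missing from the recordings")
  rows <- vector("list", length(subsets))
  for (j in seq_along(subsets)) {
    sel <- sensor_selection(subsets[[j]])
    subject_ws <- lapply(subject_urecs, function(u)
      make_windows(uniform_select(u, sel), window_s = window_s,
                   stride = stride))
    cv <- loocv(subject_ws, hp, ...)
    rows[[j]] <- data.frame(
      placements = paste(sel$placements, collapse = "+"),
      n_channels = 6L * length(sel$placements),
      mean_mae = cv$mean_mae)
    rows[[j]]$per_subject <- list(cv$per_subject_mae)
  }
  do.call(rbind, rows)
}
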