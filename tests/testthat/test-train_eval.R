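test_that("the 85/15 split partitions windows into contiguous blocks", {
  ws <- toy_window_set(N = 100L)
  sp <- split_train_val(ws, seed = 1L)
  expect_equal(n_windows(sp$train), 85L)
  expect_equal(n_windows(sp$val), 15L)
  # disjoint partition: every original window appears exactly once
  key <- function(w) apply(w$X, 3L, function(m) paste(signif(m[1, 1:5], 12),
                                                      collapse = ","))
  all_keys <- key(ws)
  got <- c(key(sp$train), key(sp$val))
  expect_setequal(got, all_keys)
  expect_length(got, length(all_keys))
  # reproducible under the seed
  sp2 <- split_train_val(ws, seed = 1L)
  expect_identical(sp$val$y, sp2$val$y)
  expect_error(split_train_val(ws_subset(ws, 1L), seed = 1L), "at least 2")
})

test_that("the validation block is contiguous within each subject", {
  ws <- ws_concat(toy_window_set(N = 40L, subject = "A", seed = 1L),
                  toy_window_set(N = 40L, subject = "B", seed = 2L))
  sp <- split_train_val(ws, seed = 3L)
  for (s in c("A", "B")) {
    # recover the per-subject validation labels in original order
    orig <- ws$y[ws$subject == s]
    val <- sp$val$y[sp$val$subject == s]
    idx <- match(val, orig)
    expect_equal(idx, seq.int(min(idx), length.out = length(idx)))
  }
})

test_that("early stopping halts exactly after the configured patience", {
  # injected sequence: improvements at checks 1 and 2, then flat
  vals <- c(3, 2, rep(2.5, 30))
  scan <- early_stop_scan(vals, patience = 20L)
  expect_equal(scan$stop_index, 22L)  # 20th consecutive non-improving check
  expect_equal(scan$best_index, 2L)
  expect_equal(scan$best, 2)
  # improvement resets the counter
  vals2 <- c(3, rep(3.5, 19), 2.9, rep(3.2, 19), 3.3)
  scan2 <- early_stop_scan(vals2, patience = 20L)
  expect_equal(scan2$stop_index, 41L)
  expect_equal(scan2$best_index, 21L)
  # sequence ending before patience runs out does not stop
  expect_true(is.na(early_stop_scan(c(3, 2, 2.5), patience = 20L)$stop_index))
})

test_that("training obeys an injected validation sequence and restores the best epoch", {
  ws <- toy_window_set(N = 24L)
  sp <- split_train_val(ws, seed = 4L)
  injected <- c(3, 2, seq(2.1, by = 0.01, length.out = 20))
  fit <- train_model(sp$train, sp$val, toy_hp(max_epochs = 50L),
                     patience = 20L, validation_metric = injected)
  expect_equal(fit$stopped_epoch, 22L)
  expect_equal(fit$best_epoch, 2L)
  expect_equal(fit$history$val_metric, injected)
})

test_that("training reduces the loss on a learnable toy problem, deterministically", {
  ws <- toy_window_set(N = 120L)
  sp <- split_train_val(ws, seed = 5L)
  fit <- train_model(sp$train, sp$val, toy_hp(max_epochs = 12L),
                     patience = 20L)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1L])
  # loss trends down over the first epochs
  expect_lt(h$train_loss[3L], h$train_loss[1L])
  expect_lt(h$train_loss[5L], h$train_loss[3L])
  fit2 <- train_model(sp$train, sp$val, toy_hp(max_epochs = 12L),
                      patience = 20L)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$par, fit2$model$par)
})

test_that("random search draws 15 in-grid configurations uniformly", {
  draws <- random_search(seed = 42L)
  expect_length(draws, 15L)
  space <- svae_search_space()
  for (d in draws) {
    expect_true(d$cfg$conv_channels %in% space$conv_channels)
    expect_true(d$cfg$hidden_size %in% space$hidden_size)
    expect_true(d$cfg$hidden_depth %in% space$hidden_depth)
    expect_true(d$cfg$latent %in% space$latent)
    expect_true(d$cfg$sine_components %in% space$sine_components)
    expect_true(d$alpha %in% space$alpha)
    expect_true(d$beta %in% space$beta)
  }
  # empirical uniformity over many draws
  many <- random_search(1e4L, seed = 43L)
  for (field in c("conv_channels", "hidden_size", "latent")) {
    vals <- vapply(many, function(d) d$cfg[[field]], numeric(1))
    freq <- table(vals) / length(vals)
    expect_length(freq, length(space[[field]]))
    expect_true(all(abs(freq - 1 / length(freq)) < 0.1 / length(freq) * length(freq)))
  }
  alphas <- vapply(many, `[[`, numeric(1), "alpha")
  freq <- table(alphas) / length(alphas)
  expect_true(all(abs(freq - 0.25) / 0.25 < 0.1))
})

test_that("the two-level MAE averages subjects with equal weight", {
  expect_equal(mean_absolute_error(list(A = c(1, 2)), list(A = c(1, 2))), 0)
  # subject A errors {1, 1}, subject B errors {3}: (1 + 3) / 2
  truths <- list(A = c(5, 6), B = 10)
  preds <- list(A = c(4, 7), B = 7)
  expect_equal(mean_absolute_error(truths, preds), 2)
  # absolute homogeneity under speed scaling
  sc <- function(l, c) lapply(l, `*`, c)
  expect_equal(mean_absolute_error(sc(truths, -3), sc(preds, -3)), 6)
  expect_error(mean_absolute_error(list(A = 1:2), list(A = 1:3)), "mismatch")
})

test_that("LOOCV runs one fold per subject and never leaks the test subject", {
  cohort <- list(A = toy_window_set(30L, seed = 1L, subject = "A"),
                 B = toy_window_set(30L, seed = 2L, subject = "B"),
                 C = toy_window_set(30L, seed = 3L, subject = "C"))
  cv <- loocv(cohort, toy_hp(max_epochs = 2L), patience = 20L, seed = 9L)
  expect_s3_class(cv, "cv_result")
  expect_length(cv$folds, 3L)
  expect_named(cv$per_subject_mae, c("A", "B", "C"))
  expect_equal(cv$mean_mae, mean(cv$per_subject_mae))
  for (f in cv$folds) {
    expect_false(f$test_subject %in% f$train_subjects)
    expect_false(f$test_subject %in% f$val_subjects)
    expect_length(f$predictions, 30L)
  }
  expect_error(loocv(cohort["A"], toy_hp()), "length")
})

test_that("the sensor study evaluates every placement subset", {
  expect_length(all_placement_subsets(), 7L)
  recs <- simulate_cohort(2L, duration = 15, seed = 5L)
  urecs <- lapply(recs, function(r) resample_uniform(convert_units(r)))
  hp <- toy_hp(max_epochs = 1L)
  tab <- sensor_combination_study(urecs, hp, stride = 2048L,
                                  patience = 20L, seed = 2L)
  expect_equal(nrow(tab), 7L)
  expect_setequal(tab$placements,
                  c("thigh", "shin", "foot", "thigh+shin", "thigh+foot",
                    "shin+foot", "thigh+shin+foot"))
  expect_equal(tab$n_channels,
               6L * (lengths(strsplit(tab$placements, "\\+"))))
  foot_only <- lapply(urecs, uniform_select, sel = "foot")
  expect_error(sensor_combination_study(foot_only, hp), "missing")
})

test_that("non-finite training loss aborts with a diagnostic", {
  ws <- toy_window_set(N = 24L)
  ws$X[1, 1, 1] <- NaN  # poisons the loss on the first epoch
  sp <- split_train_val(ws, seed = 6L)
  expect_error(train_model(sp$train, sp$val, toy_hp(max_epochs = 5L),
                           patience = 20L),
               "diverged")
})
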