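test_that("the reference configuration matches the tuned architecture", {
  cfg <- reference_config()
  expect_length(cfg$blocks, 6)
  maps <- vapply(cfg$blocks, `[[`, 0L, "feature_maps")
  kernels <- vapply(cfg$blocks, `[[`, 0L, "kernel_size")
  drops <- vapply(cfg$blocks, `[[`, 0, "dropout")
  expect_equal(maps, c(128L, 192L, 224L, 96L, 256L, 96L))
  expect_equal(kernels, c(7L, 5L, 3L, 7L, 9L, 9L))
  expect_equal(drops, c(0.3, 0.3, 0.4, 0.2, 0.3, 0.5))
  expect_equal(cfg$blocks[[3]], conv_block_spec(224, 3, 0.4))
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$batch_size, 1024L)
  expect_equal(cfg$max_epochs, 50L)
  expect_equal(cfg$early_stop_patience, 5L)
  expect_equal(cfg$loss, "binary_crossentropy")
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$head, "gap_sigmoid")
})

test_that("built networks introspect to their configuration exactly", {
  set.seed(5)
  for (rep_ in 1:3) {
    depth <- sample(2:6, 1)
    blocks <- lapply(seq_len(depth), function(i) {
      conv_block_spec(sample(c(64, 96, 128), 1), sample(c(3, 5, 7), 1),
                      sample(c(0.1, 0.3), 1))
    })
    cfg <- model_config(blocks, seed = rep_)
    layers <- model_layers(build_model(cfg))
    conv <- layers[layers$type == "conv1d", ]
    expect_equal(conv$feature_maps,
                 vapply(blocks, function(b) as.numeric(b$feature_maps), 0))
    expect_equal(conv$kernel_size,
                 vapply(blocks, function(b) as.numeric(b$kernel_size), 0))
    drop <- layers[layers$type == "dropout", ]
    expect_equal(drop$dropout, vapply(blocks, `[[`, 0, "dropout"))
    # block order conv -> batch_norm -> relu -> dropout, then GAP/dense/sigmoid
    expect_equal(layers$type,
                 c(rep(c("conv1d", "batch_norm", "relu", "dropout"), depth),
                   "global_average_pool", "dense", "sigmoid"))
  }
})

test_that("forward pass outputs probabilities and preserves temporal length", {
  m <- build_model(reference_config(seed = 2))
  X <- array(rnorm(2 * 60 * 4), c(2, 60, 4))
  fwd <- osadetect:::nn_forward(m, X, training = FALSE, keep_cache = TRUE)
  expect_true(all(fwd$prob > 0 & fwd$prob < 1))
  # first hidden block keeps 60 time-steps and has 128 feature maps
  expect_equal(dim(fwd$caches[[1]]$Z), c(2 * 60, 128))
  expect_equal(dim(fwd$A_last), c(2 * 60, 96))
})

test_that("weight initialization is reproducible from the seed", {
  cfg <- tiny_model_config(seed = 11)
  expect_identical(build_model(cfg)$params, build_model(cfg)$params)
  cfg2 <- tiny_model_config(seed = 12)
  expect_false(identical(build_model(cfg)$params, build_model(cfg2)$params))
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  cfg <- model_config(list(c(5, 3, 0), c(4, 5, 0)), seed = 3, name = "fd")
  m <- build_model(cfg)
  n <- 4
  X <- array(rnorm(n * 60 * 4), c(n, 60, 4))
  y <- rep(c(0, 1), 2)
  loss_at <- function(model) {
    osadetect:::bce_loss(y, osadetect:::nn_forward(model, X,
                                                   training = TRUE)$prob)
  }
  fwd <- osadetect:::nn_forward(m, X, training = TRUE, keep_cache = TRUE)
  grads <- osadetect:::nn_backward(m, fwd, y)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (i in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
      up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(unname(grads[[nm]][i]), fd, tolerance = 1e-4)
    }
  }
})

test_that("training separates a linearly separable toy problem", {
  tr <- toy_window_set(n_per_class = 60, patient_ids = c("a", "b"), seed = 1)
  va <- toy_window_set(n_per_class = 25, patient_ids = "c", seed = 2)
  cfg <- tiny_model_config(seed = 4, max_epochs = 10)
  fit <- train(build_model(cfg), tr, va, cfg)
  h <- fit$history
  expect_lte(h$train_loss[min(10, nrow(h))], 0.5 * h$train_loss[1])
  expect_gt(h$val_acc[nrow(h)], 0.9)
})

test_that("shared patients between train and validation are a hard failure", {
  tr <- toy_window_set(patient_ids = c("a", "b"))
  va <- toy_window_set(patient_ids = c("b", "c"))
  cfg <- tiny_model_config()
  expect_error(train(build_model(cfg), tr, va, cfg),
               class = "osadetect_leakage_error")
})

test_that("training requires both classes in both sets", {
  tr <- toy_window_set(patient_ids = c("a", "b"))
  va <- toy_window_set(patient_ids = "c")
  va1 <- osadetect:::subset_window_set(va, which(va$labels == 1L))
  cfg <- tiny_model_config()
  expect_error(train(build_model(cfg), tr, va1, cfg),
               class = "osadetect_config_error")
})

test_that("early stopping halts within patience of the best epoch and restores it", {
  tr <- toy_window_set(n_per_class = 40, patient_ids = c("a", "b"), seed = 3)
  # validation labels are pure noise, so validation loss plateaus quickly
  va <- toy_window_set(n_per_class = 20, patient_ids = "c", seed = 4)
  set.seed(5)
  va$labels <- sample(va$labels)
  cfg <- tiny_model_config(seed = 6, max_epochs = 30)
  cfg$early_stop_patience <- 3L
  fit <- train(build_model(cfg), tr, va, cfg)
  expect_lte(nrow(fit$history), fit$best_epoch + 3)
  # restored weights reproduce the recorded best validation loss
  p <- predict_windows(fit, va)
  expect_equal(osadetect:::bce_loss(va$labels, p$probability),
               fit$best_val_loss, tolerance = 1e-6)
  expect_equal(min(fit$history$val_loss), fit$best_val_loss,
               tolerance = 1e-12)
})

test_that("training runs the full budget while validation keeps improving", {
  tr <- toy_window_set(n_per_class = 40, patient_ids = c("a", "b"), seed = 3)
  va <- toy_window_set(n_per_class = 20, patient_ids = "c", seed = 4)
  cfg <- tiny_model_config(seed = 6, max_epochs = 6)
  fit <- train(build_model(cfg), tr, va, cfg)
  # on the separable problem validation loss falls monotonically here
  expect_equal(fit$best_epoch, nrow(fit$history))
})

test_that("prediction applies the tie-positive threshold rule monotonically", {
  tr <- toy_window_set(n_per_class = 30, patient_ids = c("a", "b"))
  cfg <- tiny_model_config(seed = 2, max_epochs = 2)
  fit <- train(build_model(cfg), tr,
               toy_window_set(n_per_class = 10, patient_ids = "c"), cfg)
  ws <- toy_window_set(n_per_class = 15, patient_ids = "d", seed = 9)
  pred <- predict_windows(fit, ws)
  # a probability exactly equal to the threshold is predicted positive
  thr <- pred$probability[3]
  pred_tie <- predict_windows(fit, ws, threshold = thr)
  expect_equal(pred_tie$prediction[3], 1L)
  n_pos <- vapply(c(0.4, 0.5, 0.6), function(t) {
    sum(predict_windows(fit, ws, threshold = t)$prediction)
  }, 0)
  expect_true(all(diff(n_pos) <= 0))
  # deterministic inference
  expect_identical(pred$probability, predict_windows(fit, ws)$probability)
  bad <- ws; bad$windows <- ws$windows[, , 1:3, drop = FALSE]
  expect_error(predict_windows(fit, bad), class = "osadetect_shape_error")
})

test_that("the tuner samples from the declared space and is reproducible", {
  tr <- toy_window_set(n_per_class = 25, patient_ids = c("a", "b"))
  va <- toy_window_set(n_per_class = 10, patient_ids = "c", seed = 2)
  budget <- list(n_candidates = 5, rungs = 2, keep_fraction = 1 / 2,
                 max_epochs = 2)
  base <- tiny_model_config(max_epochs = 2)
  r1 <- tune(search_space(), tr, va, budget, seed = 3, base_config = base)
  r2 <- tune(search_space(), tr, va, budget, seed = 3, base_config = base)
  expect_identical(r1$val_accuracy, r2$val_accuracy)
  expect_identical(r1$config, r2$config)
  for (cfg in r1$config) {
    for (b in cfg$blocks) {
      expect_true(b$kernel_size %in% c(3, 5, 7, 9, 11))
      expect_true(b$feature_maps %in% c(64, 96, 128, 160, 192, 224, 256))
      expect_true(b$dropout %in% seq(0.1, 0.5, 0.1))
    }
    expect_true(length(cfg$blocks) %in% 2:6)
  }
})

test_that("a single-rung full-keep schedule is plain random search", {
  tr <- toy_window_set(n_per_class = 25, patient_ids = c("a", "b"))
  va <- toy_window_set(n_per_class = 10, patient_ids = "c", seed = 2)
  res <- tune(search_space(), tr, va,
              budget = list(n_candidates = 4, rungs = 1, keep_fraction = 1,
                            max_epochs = 2),
              seed = 8, base_config = tiny_model_config(max_epochs = 2))
  expect_equal(nrow(res), 4)
  expect_true(!is.unsorted(rev(res$val_accuracy)))
  expect_equal(res$rank, 1:4)
  expect_error(tune(list(), tr, va), class = "osadetect_config_error")
})

test_that("model checkpoints round-trip with their JSON sidecar", {
  cfg <- tiny_model_config(seed = 3)
  m <- build_model(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$learning_rate, cfg$learning_rate)
  expect_equal(nrow(side$blocks), 2)
})
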