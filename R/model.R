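#' Specify one convolutional block
#'
#' Each hidden block of the window classifier is a length-preserving 1-D
#' convolution (stride 1, zero "same" padding) followed by batch
#' normalization, ReLU and element-wise dropout.
#'
#' @param feature_maps Number of convolution filters.
#' @param kernel_size Odd temporal kernel width.
#' @param dropout Dropout rate in `[0, 1)` applied after the activation.
#' @return A `conv_block_spec` list.
#' @export
conv_block_spec <- function(feature_maps, kernel_size, dropout) {
  stopifnot(feature_maps >= 1, kernel_size >= 1, kernel_size %% 2 == 1,
            dropout >= 0, dropout < 1)
  structure(list(feature_maps = as.integer(feature_maps),
                 kernel_size = as.integer(kernel_size),
                 dropout = dropout),
            class = "conv_block_spec")
}

#' Full hyperparameter bundle of the window classifier
#'
#' @param blocks List of 2-6 [conv_block_spec()]s.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (best-epoch weights are restored).
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @param decision_threshold Probability cutoff for the positive class
#'   (ties predict positive).
#' @param name Optional profile name.
#' @return A `model_config` list. The head is fixed: global average pooling
#'   over time, a single dense unit and a sigmoid, trained with Adam on
#'   binary cross-entropy.
#' @export
model_config <- function(blocks, learning_rate = 0.001, batch_size = 1024L,
                         max_epochs = 50L, early_stop_patience = 5L,
                         seed = 1L, decision_threshold = 0.5,
                         name = "custom") {
  if (length(blocks) < 2 || length(blocks) > 6) {
    abort("between 2 and 6 convolutional blocks are supported",
          class = "osadetect_config_error")
  }
  blocks <- lapply(blocks, function(b) {
    if (inherits(b, "conv_block_spec")) b
    else conv_block_spec(b[[1]], b[[2]], b[[3]])
  })
  stopifnot(learning_rate > 0, decision_threshold > 0, decision_threshold < 1)
  structure(list(blocks = blocks, conv_activation = "relu",
                 head = "gap_sigmoid", optimizer = "adam",
                 loss = "binary_crossentropy",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 name = name),
            class = "model_config")
}

#' The reference six-block architecture
#'
#' The tuned architecture used throughout the analysis: six convolutional
#' blocks with feature maps 128, 192, 224, 96, 256, 96, kernel sizes 7, 5,
#' 3, 7, 9, 9 and dropouts 0.3, 0.3, 0.4, 0.2, 0.3, 0.5; GAP + sigmoid head;
#' Adam at learning rate 0.001 on binary cross-entropy; batch size 1,024;
#' at most 50 epochs with patience-5 early stopping.
#'
#' @param seed Seed stored in the config.
#' @return A [model_config()].
#' @export
reference_config <- function(seed = 1L) {
  model_config(
    blocks = list(conv_block_spec(128, 7, 0.3),
                  conv_block_spec(192, 5, 0.3),
                  conv_block_spec(224, 3, 0.4),
                  conv_block_spec(96, 7, 0.2),
                  conv_block_spec(256, 9, 0.3),
                  conv_block_spec(96, 9, 0.5)),
    learning_rate = 0.001, batch_size = 1024L, max_epochs = 50L,
    early_stop_patience = 5L, seed = seed, name = "reference")
}

#' CPU-scale training profile
#'
#' A reduced two-block profile (32 feature maps per block, batch 128, at
#' most 20 epochs) for desk-scale experiments on synthetic cohorts; the
#' six-block [reference_config()] remains the reference architecture.
#'
#' @param seed Seed stored in the config.
#' @param max_epochs Cap on training epochs (default 20).
#' @return A [model_config()].
#' @export
scaled_down_config <- function(seed = 1L, max_epochs = 20L) {
  model_config(
    blocks = list(conv_block_spec(32, 7, 0.1),
                  conv_block_spec(32, 5, 0.1)),
    learning_rate = 0.003, batch_size = 128L, max_epochs = max_epochs,
    early_stop_patience = 5L, seed = seed, name = "scaled_down")
}

#' Build (initialize) the window classifier
#'
#' Instantiates the network described by a [model_config()]: per block a
#' length-preserving 1-D convolution, batch normalization, ReLU and dropout;
#' then a temporal global average pool, one dense unit and a sigmoid
#' probability output. Weights are initialized from `config$seed`, so two
#' builds with the same seed are identical.
#'
#' @param config A [model_config()].
#' @param n_channels Number of input channels (4).
#' @return An `osa_model` object.
#' @export
build_model <- function(config, n_channels = 4L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  init <- nn_init_params(config, n_channels)
  structure(list(config = config, n_channels = as.integer(n_channels),
                 params = init$params, running = init$running,
                 trained = FALSE, train_variant_flags = NULL),
            class = "osa_model")
}

as_osa_model <- function(x) {
  if (inherits(x, "osa_train_result")) x$model
  else if (inherits(x, "osa_model")) x
  else abort("expected an `osa_model` or `osa_train_result`")
}

#' @export
print.osa_model <- function(x, ...) {
  cat(sprintf("<osa_model> '%s': %d conv blocks, GAP + sigmoid head, %s\n",
              x$config$name, length(x$config$blocks),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Introspect the built network layer by layer
#'
#' Reads the layer sequence off the actual weight tensors (not the config
#' echo), for architecture audits.
#'
#' @param model An `osa_model` or `osa_train_result`.
#' @return A tibble with columns `layer`, `type`, `feature_maps`,
#'   `kernel_size`, `dropout`.
#' @export
model_layers <- function(model) {
  model <- as_osa_model(model)
  rows <- list()
  c_in <- model$n_channels
  for (l in seq_along(model$config$blocks)) {
    W <- model$params[[paste0("blk", l, "_W")]]
    f <- ncol(W)
    k <- nrow(W) %/% c_in
    rate <- model$config$blocks[[l]]$dropout
    rows[[length(rows) + 1]] <- tibble::tibble(
      type = c("conv1d", "batch_norm", "relu", "dropout"),
      feature_maps = c(f, f, NA, NA),
      kernel_size = c(k, NA, NA, NA),
      dropout = c(NA, NA, NA, rate))
    c_in <- f
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    type = c("global_average_pool", "dense", "sigmoid"),
    feature_maps = c(NA, 1, NA), kernel_size = NA_real_, dropout = NA_real_)
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, layer = dplyr::row_number(), .before = 1)
}

check_window_tensor <- function(X) {
  d <- dim(X)
  if (length(d) != 3 || d[2] != 60) {
    abort("window tensor must be n x 60 x channels",
          class = "osadetect_shape_error")
  }
}

#' Train the window classifier
#'
#' Optimizes binary cross-entropy with Adam on patient-disjoint training and
#' validation window sets. Early stopping monitors the validation loss with
#' the configured patience and restores the best-epoch weights (including
#' batch-norm running statistics). Fully reproducible given `config$seed`.
#'
#' @param model An `osa_model` from [build_model()] (or `NULL` to build from
#'   `config`).
#' @param train_ws,val_ws [window_set()]s with disjoint patient ids, both
#'   containing both classes.
#' @param config A [model_config()]; defaults to the model's own.
#' @return An `osa_train_result`: the trained model, a per-epoch `history`
#'   tibble (train/validation loss and accuracy), and `best_epoch`.
#' @export
train <- function(model, train_ws, val_ws, config = NULL) {
  config <- config %||% model$config
  if (is.null(model)) model <- build_model(config)
  shared <- intersect(unique(train_ws$patient_ids), unique(val_ws$patient_ids))
  if (length(shared) > 0) {
    abort(sprintf("patient(s) %s appear in both train and validation sets",
                  paste(shared, collapse = ", ")),
          class = "osadetect_leakage_error")
  }
  for (ws in list(train_ws, val_ws)) {
    if (length(unique(ws$labels)) < 2) {
      abort("train and validation sets must both contain both classes",
            class = "osadetect_config_error")
    }
  }
  check_window_tensor(train_ws$windows)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- length(train_ws$labels)
  y <- train_ws$labels
  state <- adam_init(model$params)
  best <- list(val_loss = Inf, epoch = 0L, params = NULL, running = NULL)
  hist <- vector("list", config$max_epochs)

  eval_set <- function(ws) {
    p <- nn_predict_prob(model, ws$windows)
    c(loss = bce_loss(ws$labels, p),
      acc = mean((p >= config$decision_threshold) == (ws$labels == 1L)))
  }

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    at <- 1L
    loss_sum <- 0
    hit_sum <- 0
    while (at <= n) {
      take <- idx[at:min(at + config$batch_size - 1L, n)]
      fwd <- nn_forward(model, train_ws$windows[take, , , drop = FALSE],
                        training = TRUE, keep_cache = TRUE)
      model$running <- fwd$running
      grads <- nn_backward(model, fwd, y[take])
      upd <- adam_step(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      loss_sum <- loss_sum + bce_loss(y[take], fwd$prob) * length(take)
      hit_sum <- hit_sum +
        sum((fwd$prob >= config$decision_threshold) == (y[take] == 1L))
      at <- at + config$batch_size
    }
    # train metrics are running means over the epoch's mini-batches (dropout
    # and batch statistics active); validation is a full inference pass
    tr <- c(loss = loss_sum / n, acc = hit_sum / n)
    va <- eval_set(val_ws)
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = tr["loss"], train_acc = tr["acc"],
                                    val_loss = va["loss"], val_acc = va["acc"])
    if (va["loss"] < best$val_loss - 1e-12) {
      best <- list(val_loss = va["loss"], epoch = epoch,
                   params = model$params, running = model$running)
    }
    if (epoch - best$epoch >= config$early_stop_patience) break
  }

  model$params <- best$params
  model$running <- best$running
  model$trained <- TRUE
  model$train_variant_flags <- train_ws$variant_flags
  structure(list(model = model,
                 history = dplyr::bind_rows(hist[!vapply(hist, is.null, TRUE)]),
                 best_epoch = best$epoch,
                 best_val_loss = unname(best$val_loss),
                 config = config),
            class = "osa_train_result")
}

#' @export
print.osa_train_result <- function(x, ...) {
  last <- x$history[x$history$epoch == x$best_epoch, ]
  cat(sprintf(
    "<osa_train_result> %d epochs run, best epoch %d (val loss %.4f, val acc %.3f)\n",
    nrow(x$history), x$best_epoch, last$val_loss, last$val_acc))
  invisible(x)
}

#' @method tidy osa_train_result
#' @export
tidy.osa_train_result <- function(x, ...) x$history

#' @method glance osa_train_result
#' @export
glance.osa_train_result <- function(x, ...) {
  best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
                 train_loss = best$train_loss, train_acc = best$train_acc,
                 val_loss = best$val_loss, val_acc = best$val_acc)
}

#' @method autoplot osa_train_result
#' @export
autoplot.osa_train_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = c("set", "metric"), names_sep = "_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Score windows with a trained model
#'
#' @param model An `osa_model` or `osa_train_result`.
#' @param ws A [window_set()] preprocessed like the training variant.
#' @param threshold Decision threshold; a window is predicted positive iff
#'   its probability is `>= threshold` (ties positive).
#' @return A tibble with `patient_id`, `window_start_s`, `label`,
#'   `probability` and `prediction`.
#' @export
predict_windows <- function(model, ws, threshold = 0.5) {
  model <- as_osa_model(model)
  check_window_tensor(ws$windows)
  if (dim(ws$windows)[3] != model$n_channels) {
    abort("window tensor channel count does not match the model",
          class = "osadetect_shape_error")
  }
  if (!is.null(model$train_variant_flags) &&
      !identical(ws$variant_flags$standardized,
                 model$train_variant_flags$standardized)) {
    warn("window-set standardization differs from the model's training variant")
  }
  p <- nn_predict_prob(model, ws$windows)
  tibble::tibble(patient_id = ws$patient_ids,
                 window_start_s = ws$window_start_s,
                 label = ws$labels,
                 probability = p,
                 prediction = as.integer(p >= threshold))
}

#' The tuner's hyperparameter search space
#'
#' Depth 2-6 blocks; per-layer feature maps from
#' `{64, 96, 128, 160, 192, 224, 256}`, kernel sizes from `{3, 5, 7, 9, 11}`
#' and dropouts from `{0.1, ..., 0.5}`. ReLU convolutions, sigmoid head,
#' Adam and binary cross-entropy are fixed, not searched.
#'
#' @return A named list of candidate value sets.
#' @export
search_space <- function() {
  list(depth = 2:6,
       feature_maps = c(64L, 96L, 128L, 160L, 192L, 224L, 256L),
       kernel_sizes = c(3L, 5L, 7L, 9L, 11L),
       dropouts = seq(0.1, 0.5, by = 0.1))
}

sample_config <- function(space, base, seed) {
  depth <- sample(space$depth, 1)
  blocks <- lapply(seq_len(depth), function(i) {
    conv_block_spec(sample(space$feature_maps, 1),
                    sample(space$kernel_sizes, 1),
                    sample(space$dropouts, 1))
  })
  model_config(blocks, learning_rate = base$learning_rate,
               batch_size = base$batch_size, max_epochs = base$max_epochs,
               early_stop_patience = base$early_stop_patience,
               seed = seed, name = "tuner")
}

#' Successive-halving hyperparameter search
#'
#' Samples `n_candidates` configurations uniformly from the search space,
#' trains each for the first rung's epoch budget, keeps the best
#' `keep_fraction` by validation accuracy, multiplies the epoch budget by
#' `1/keep_fraction` per rung and repeats until the rungs are exhausted or
#' `max_epochs` reached. With `keep_fraction = 1` and one rung this reduces
#' to plain random search.
#'
#' @param space Search space from [search_space()].
#' @param train_ws,val_ws Patient-disjoint window sets.
#' @param budget List with `n_candidates`, `rungs`, `keep_fraction`,
#'   `max_epochs`.
#' @param seed Integer seed driving sampling and candidate training.
#' @param base_config Training controls (batch size, learning rate, patience)
#'   shared by all candidates.
#' @return A tibble ranked by final validation accuracy with columns `rank`,
#'   `config` (list-column of [model_config()]), `val_accuracy`,
#'   `epochs_budget`; the top three rows are the candidates retained for
#'   downstream cross-validation.
#' @export
tune <- function(space, train_ws, val_ws,
                 budget = list(n_candidates = 90, rungs = 3,
                               keep_fraction = 1 / 3, max_epochs = 50),
                 seed = 1L, base_config = scaled_down_config()) {
  if (length(space) == 0 || length(space$depth) == 0) {
    abort("empty search space", class = "osadetect_config_error")
  }
  stopifnot(budget$n_candidates >= 1, budget$rungs >= 1,
            budget$keep_fraction > 0, budget$keep_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% 2147483647)
  grow <- 1 / budget$keep_fraction
  e1 <- max(1L, floor(budget$max_epochs / grow^(budget$rungs - 1)))
  configs <- lapply(seq_len(budget$n_candidates), function(i) {
    sample_config(space, base_config, seed = (seed + i) %% 2147483647)
  })
  alive <- seq_along(configs)
  acc <- rep(NA_real_, length(configs))
  epochs <- e1
  for (rung in seq_len(budget$rungs)) {
    epochs_r <- as.integer(min(round(epochs), budget$max_epochs))
    for (i in alive) {
      cfg <- configs[[i]]
      cfg$max_epochs <- epochs_r
      cfg$early_stop_patience <- max(cfg$early_stop_patience, epochs_r)
      res <- train(build_model(cfg), train_ws, val_ws, cfg)
      acc[i] <- res$history$val_acc[nrow(res$history)]
    }
    if (rung < budget$rungs) {
      n_keep <- max(1L, ceiling(length(alive) * budget$keep_fraction))
      alive <- alive[order(-acc[alive])][seq_len(n_keep)]
      epochs <- epochs * grow
    }
  }
  ord <- order(-acc, seq_along(acc))
  survivors <- ord[ord %in% alive]
  tibble::tibble(rank = seq_along(survivors),
                 config = configs[survivors],
                 val_accuracy = acc[survivors],
                 epochs_budget = as.integer(min(round(epochs),
                                                budget$max_epochs)))
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS of the model object plus a JSON sidecar of its
#' configuration.
#'
#' @param model An `osa_model` or `osa_train_result`.
#' @param path Checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `path` (or the model, for the loader), invisibly.
#' @export
save_model <- function(model, path) {
  model <- as_osa_model(model)
  saveRDS(model, path)
  cfg <- model$config
  cfg$blocks <- lapply(cfg$blocks, unclass)
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
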