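#' Grad-CAM temporal relevance for one window
#'
#' Computes the gradient of the target-class score with respect to the last
#' convolutional block's feature maps `A_k(t)`, averages it over time to get
#' the channel weights `alpha_k`, and forms the map
#' `L(t) = ReLU(sum_k alpha_k A_k(t))`, normalized by its maximum. With the
#' single-logit sigmoid head the class-1 score is the pre-sigmoid logit and
#' the class-0 score its negation (the standard binary adaptation); through
#' the global average pool the gradient of the logit w.r.t. `A_k(t)` is
#' `w_k / T`, which is what the closed-form backward pass below evaluates.
#' By default the map targets the predicted class.
#'
#' @param model A trained `osa_model` or `osa_train_result`.
#' @param window Numeric 60 x 4 matrix, preprocessed like the model's
#'   training variant.
#' @param target_class 0, 1, or `NULL` (default: the predicted class).
#' @return A `relevance_map`: list with `relevance` (length 60, in `[0, 1]`),
#'   `probability`, `target_class`, `null_saliency` flag, `source_layer`,
#'   and the `window` itself.
#' @export
grad_cam <- function(model, window, target_class = NULL) {
  model <- as_osa_model(model)
  if (length(model$config$blocks) < 1) {
    abort("model has no convolutional layers",
          class = "osadetect_config_error")
  }
  stopifnot(is.matrix(window), nrow(window) == 60,
            ncol(window) == model$n_channels)
  X <- array(window, c(1, 60, model$n_channels))
  fwd <- nn_forward(model, X, training = FALSE)
  prob <- fwd$prob
  if (is.null(target_class)) target_class <- as.integer(prob >= 0.5)
  T_ <- fwd$T_
  A <- fwd$A_last                          # T x F activations of last block
  sign_ <- if (target_class == 1L) 1 else -1
  alpha <- sign_ * as.vector(model$params$dense_w) / T_
  raw <- pmax(as.vector(A %*% alpha), 0)
  if (length(raw) != 60) {
    raw <- approx(seq_along(raw), raw, n = 60)$y
  }
  mx <- max(raw)
  null_saliency <- mx <= 0
  relevance <- if (null_saliency) rep(0, 60) else raw / mx
  structure(list(relevance = relevance, probability = prob,
                 target_class = as.integer(target_class),
                 null_saliency = null_saliency,
                 source_layer = paste0("conv_block_",
                                       length(model$config$blocks)),
                 window = window),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("<relevance_map> class %d, p=%.3f%s; peak at t=%ds\n",
              x$target_class, x$probability,
              if (x$null_saliency) " [null saliency]" else "",
              which.max(x$relevance) - 1))
  invisible(x)
}

#' Occlusion-based relevance oracle
#'
#' Model-agnostic attribution used to validate Grad-CAM: every `span_s`-long
#' span of the window (all channels) is replaced by the per-channel window
#' mean and the drop in the target-class probability is recorded; a second's
#' relevance is the mean drop over the spans covering it. No normalization
#' is applied.
#'
#' @param model A trained `osa_model` or `osa_train_result`.
#' @param window Numeric 60 x 4 matrix.
#' @param target_class 0 or 1.
#' @param span_s Occlusion span length in seconds (1-60); a 60-s span gives
#'   a single global value broadcast to all seconds.
#' @return Numeric vector of length 60.
#' @export
occlusion_relevance <- function(model, window, target_class, span_s = 10) {
  model <- as_osa_model(model)
  stopifnot(is.matrix(window), nrow(window) == 60, span_s >= 1, span_s <= 60)
  mu <- colMeans(window)
  n_spans <- 60 - span_s + 1
  X <- array(0, c(n_spans + 1, 60, ncol(window)))
  X[1, , ] <- window
  for (s in seq_len(n_spans)) {
    w <- window
    w[s:(s + span_s - 1), ] <- matrix(mu, span_s, ncol(window), byrow = TRUE)
    X[s + 1, , ] <- w
  }
  p <- nn_predict_prob(model, X)
  if (target_class == 0L) p <- 1 - p
  drops <- p[1] - p[-1]
  rel <- numeric(60)
  cover <- numeric(60)
  for (s in seq_len(n_spans)) {
    idx <- s:(s + span_s - 1)
    rel[idx] <- rel[idx] + drops[s]
    cover[idx] <- cover[idx] + 1
  }
  rel / cover
}

#' Render a window with its relevance overlay
#'
#' Draws the four channel traces stacked on a shared time axis, shaded by
#' the temporal relevance map (one shared map across channels, as the input
#' channels are mixed by the first convolution), and writes the figure to
#' file. The title reports the predicted probability and the true label.
#'
#' @param window Numeric 60 x 4 matrix.
#' @param relevance A `relevance_map` from [grad_cam()].
#' @param out_path Output image path (extension selects the device, e.g.
#'   `.png` or `.pdf`).
#' @param true_label Optional true window label for the title.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(window, relevance, out_path, true_label = NA) {
  p <- autoplot.relevance_map(relevance, true_label = true_label)
  dir <- dirname(out_path)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot write to %s: directory does not exist", out_path),
          class = "osadetect_io_error")
  }
  ggplot2::ggsave(out_path, p, width = 7, height = 6, dpi = 120)
  invisible(out_path)
}

#' @rdname render_overlay
#' @param object A `relevance_map`.
#' @param ... Unused.
#' @method autoplot relevance_map
#' @export
autoplot.relevance_map <- function(object, ..., true_label = NA) {
  window <- object$window
  df <- tibble::tibble(
    time_s = rep(0:59, times = 4),
    channel = factor(rep(CHANNELS, each = 60), levels = CHANNELS),
    value = as.vector(window))
  shade <- tibble::tibble(time_s = 0:59, relevance = object$relevance)
  title <- sprintf("p(apnea) = %.3f, target class %d%s",
                   object$probability, object$target_class,
                   if (!is.na(true_label)) sprintf(", true label %s", true_label)
                   else "")
  ggplot2::ggplot() +
    ggplot2::geom_tile(
      data = tidyr::crossing(shade, channel = factor(CHANNELS, levels = CHANNELS)),
      ggplot2::aes(x = .data$time_s, y = 0, fill = .data$relevance),
      height = Inf, alpha = 0.9) +
    ggplot2::geom_line(data = df,
                       ggplot2::aes(x = .data$time_s, y = .data$value),
                       linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::scale_fill_gradient(low = "white", high = "#ffcc00",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "time in window (s)", y = NULL, title = title,
                  fill = "relevance") +
    ggplot2::theme_minimal()
}
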