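# 1-D CNN engine. Windows are (n, T=60, C=4) arrays; internally each batch
# is a (n*T) x C matrix with rows ordered time-fastest within each window,
# so a temporal convolution becomes an im2col gather plus one BLAS matmul.
# Convolutions are length-preserving (zero "same" padding, stride 1); the
# only temporal reduction is the global average pool before the dense head,
# which keeps the last convolutional layer aligned 1:1 with seconds for
# Grad-CAM.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

to_rows <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2, 1, 3)), d[1] * d[2], d[3])
}

# (n*T) x C -> (n*T) x (k*C), offset-major column blocks; zero padding at
# window boundaries.
im2col <- function(Xm, n, T_, k) {
  p <- (k - 1) %/% 2
  nT <- n * T_
  tvec <- rep(seq_len(T_), times = n)
  C <- ncol(Xm)
  out <- matrix(0, nT, k * C)
  for (j in seq_len(k)) {
    o <- j - p - 1L
    valid <- tvec + o >= 1L & tvec + o <= T_
    cols <- (j - 1L) * C + seq_len(C)
    out[valid, cols] <- Xm[which(valid) + o, , drop = FALSE]
  }
  out
}

# Scatter-add the im2col gradient back onto the input rows.
col2im <- function(dcol, n, T_, k, C) {
  p <- (k - 1) %/% 2
  nT <- n * T_
  tvec <- rep(seq_len(T_), times = n)
  dXm <- matrix(0, nT, C)
  for (j in seq_len(k)) {
    o <- j - p - 1L
    valid <- tvec + o >= 1L & tvec + o <= T_
    cols <- (j - 1L) * C + seq_len(C)
    idx <- which(valid) + o
    dXm[idx, ] <- dXm[idx, ] + dcol[valid, cols, drop = FALSE]
  }
  dXm
}

# Seeded parameter initialization (He-scaled conv weights).
nn_init_params <- function(config, n_channels = 4L) {
  params <- list()
  running <- list()
  c_in <- n_channels
  for (l in seq_along(config$blocks)) {
    blk <- config$blocks[[l]]
    k <- blk$kernel_size; f <- blk$feature_maps
    params[[paste0("blk", l, "_W")]] <-
      matrix(rnorm(k * c_in * f, 0, sqrt(2 / (k * c_in))), k * c_in, f)
    params[[paste0("blk", l, "_b")]] <- numeric(f)
    params[[paste0("blk", l, "_gamma")]] <- rep(1, f)
    params[[paste0("blk", l, "_beta")]] <- numeric(f)
    running[[l]] <- list(mean = numeric(f), var = rep(1, f))
    c_in <- f
  }
  params$dense_w <- matrix(rnorm(c_in, 0, sqrt(1 / c_in)), c_in, 1)
  params$dense_b <- 0
  list(params = params, running = running)
}

# Forward pass. training=TRUE uses batch statistics (and updates a copy of
# the running stats, returned in the result) and applies inverted dropout.
nn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  d <- dim(X)
  n <- d[1]; T_ <- d[2]
  pr <- model$params
  running <- model$running
  A <- to_rows(X)
  caches <- if (keep_cache) vector("list", length(cfg$blocks))
  for (l in seq_along(cfg$blocks)) {
    blk <- cfg$blocks[[l]]
    k <- blk$kernel_size
    col <- im2col(A, n, T_, k)
    Y <- col %*% pr[[paste0("blk", l, "_W")]]
    Y <- sweep(Y, 2, pr[[paste0("blk", l, "_b")]], "+")
    if (training) {
      mu <- colMeans(Y)
      v <- colMeans(Y^2) - mu^2
      v[v < 0] <- 0
      running[[l]]$mean <- BN_MOMENTUM * running[[l]]$mean + (1 - BN_MOMENTUM) * mu
      running[[l]]$var <- BN_MOMENTUM * running[[l]]$var + (1 - BN_MOMENTUM) * v
    } else {
      mu <- running[[l]]$mean
      v <- running[[l]]$var
    }
    inv <- 1 / sqrt(v + BN_EPS)
    gamma <- pr[[paste0("blk", l, "_gamma")]]
    beta <- pr[[paste0("blk", l, "_beta")]]
    if (training || keep_cache) {
      xhat <- sweep(sweep(Y, 2, mu), 2, inv, "*")
      Z <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    } else {
      # inference: batch-norm folds into one affine map per feature
      xhat <- NULL
      Z <- sweep(sweep(Y, 2, gamma * inv, "*"), 2, beta - mu * gamma * inv, "+")
    }
    R <- Z * (Z > 0)
    mask <- NULL
    if (training && blk$dropout > 0) {
      mask <- matrix((runif(length(R)) >= blk$dropout) / (1 - blk$dropout),
                     nrow(R), ncol(R))
      A_out <- R * mask
    } else {
      A_out <- R
    }
    if (keep_cache) {
      caches[[l]] <- list(col = col, inv = inv, xhat = xhat, Z = Z, mask = mask)
    }
    A <- A_out
  }
  grp <- rep(seq_len(n), each = T_)
  Zg <- rowsum(A, grp) / T_                   # n x F
  logit <- as.vector(Zg %*% pr$dense_w) + pr$dense_b
  prob <- stats::plogis(logit)
  list(prob = prob, logit = logit, A_last = A, Zg = Zg, caches = caches,
       n = n, T_ = T_, running = running)
}

# Gradients of the mean clipped binary cross-entropy w.r.t. every trainable
# parameter; requires a forward pass with keep_cache = TRUE.
nn_backward <- function(model, fwd, y) {
  cfg <- model$config
  pr <- model$params
  n <- fwd$n; T_ <- fwd$T_
  grads <- list()
  dlogit <- (fwd$prob - y) / n
  grads$dense_w <- crossprod(fwd$Zg, dlogit)
  grads$dense_b <- sum(dlogit)
  dZg <- matrix(dlogit, n, 1) %*% t(pr$dense_w)   # n x F
  dA <- dZg[rep(seq_len(n), each = T_), , drop = FALSE] / T_
  for (l in rev(seq_along(cfg$blocks))) {
    cc <- fwd$caches[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dZ <- dA * (cc$Z > 0)
    gamma <- pr[[paste0("blk", l, "_gamma")]]
    grads[[paste0("blk", l, "_gamma")]] <- colSums(dZ * cc$xhat)
    grads[[paste0("blk", l, "_beta")]] <- colSums(dZ)
    dxhat <- sweep(dZ, 2, gamma, "*")
    m <- nrow(dxhat)
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * cc$xhat)
    dY <- sweep(sweep(dxhat, 2, s1) - sweep(cc$xhat, 2, s2, "*"), 2,
                cc$inv, "*")
    W <- pr[[paste0("blk", l, "_W")]]
    grads[[paste0("blk", l, "_W")]] <- crossprod(cc$col, dY)
    grads[[paste0("blk", l, "_b")]] <- colSums(dY)
    if (l > 1) {
      dcol <- dY %*% t(W)
      c_in <- cfg$blocks[[l - 1]]$feature_maps
      dA <- col2im(dcol, n, T_, cfg$blocks[[l]]$kernel_size, c_in)
    }
  }
  grads
}

bce_loss <- function(y, p, clip = 1e-7) {
  pc <- pmin(pmax(p, clip), 1 - clip)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Batched inference probabilities for an (n, 60, 4) array.
nn_predict_prob <- function(model, X, batch = 512L) {
  n <- dim(X)[1]
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  at <- 1L
  while (at <= n) {
    hi <- min(at + batch - 1L, n)
    out[at:hi] <- nn_forward(model, X[at:hi, , , drop = FALSE],
                             training = FALSE)$prob
    at <- hi + 1L
  }
  out
}
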