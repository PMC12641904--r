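# A small 1-D convolutional network for classifying 50-point recovery
# curves, written directly on R matrices. Layout conventions:
#   activations: array(batch, length, channels), batch fastest in memory
#   conv weights: matrix (kernel * in_channels) x filters, kernel index
#     fastest within each input channel; valid (no-padding) convolution
# The network is conv(ReLU)-pool-conv(ReLU)-pool-dense(ReLU)-dropout-
# softmax(2), trained with Adam on categorical cross-entropy with early
# stopping on validation loss.

#' Cross-validation and network configuration
#'
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed RNG seed controlling fold assignment, weight initialisation,
#'   batch shuffling and dropout.
#' @param stratified Stratify folds by class (default `TRUE`; with 14 + 14
#'   subjects unstratified folds easily lose a class).
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before training halts (default 10).
#' @param max_epochs Maximum training epochs (default 200); 0 leaves the
#'   network untrained.
#' @param batch_size Minibatch size (default 4).
#' @param val_fraction Fraction of the training fold carved out (stratified)
#'   as the inner validation split for early stopping (default 0.25).
#' @param filters Filters of the two convolution blocks (default 16, 32).
#' @param kernel_size Convolution kernel length (default 5).
#' @param pool_size Max-pooling width/stride (default 2).
#' @param dense_units Width of the dense layer (default 32).
#' @param dropout_rate Dropout probability on the dense activation
#'   (default 0.3).
#' @param learning_rate Adam step size (default 1e-3).
#' @return A `plr_cv_config` list.
#' @export
cv_config <- function(n_folds = 5, seed = 1L, stratified = TRUE,
                      early_stopping_patience = 10, max_epochs = 200,
                      batch_size = 4, val_fraction = 0.25,
                      filters = c(16L, 32L), kernel_size = 5L,
                      pool_size = 2L, dense_units = 32L,
                      dropout_rate = 0.3, learning_rate = 1e-3) {
  stopifnot(n_folds >= 2, early_stopping_patience >= 1, max_epochs >= 0,
            batch_size >= 1, val_fraction > 0, val_fraction < 1,
            length(filters) == 2, kernel_size >= 1, pool_size >= 1,
            dense_units >= 1, dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0)
  structure(
    list(n_folds = as.integer(n_folds), seed = as.integer(seed),
         stratified = stratified,
         early_stopping_patience = as.integer(early_stopping_patience),
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         val_fraction = val_fraction,
         filters = as.integer(filters), kernel_size = as.integer(kernel_size),
         pool_size = as.integer(pool_size),
         dense_units = as.integer(dense_units),
         dropout_rate = dropout_rate, learning_rate = learning_rate),
    class = "plr_cv_config"
  )
}

im2col <- function(x, k) {
  b <- dim(x)[1]; l <- dim(x)[2]; ch <- dim(x)[3]
  l_out <- l - k + 1
  cols <- matrix(0, b * l_out, k * ch)
  for (c_i in seq_len(ch)) {
    for (j in seq_len(k)) {
      cols[, (c_i - 1L) * k + j] <- as.vector(x[, j:(j + l_out - 1), c_i])
    }
  }
  cols
}

col2im_add <- function(dcols, b, l, ch, k) {
  l_out <- l - k + 1
  dx <- array(0, c(b, l, ch))
  for (c_i in seq_len(ch)) {
    for (j in seq_len(k)) {
      dx[, j:(j + l_out - 1), c_i] <- dx[, j:(j + l_out - 1), c_i] +
        matrix(dcols[, (c_i - 1L) * k + j], b, l_out)
    }
  }
  dx
}

maxpool_fwd <- function(x, p) {
  b <- dim(x)[1]; l <- dim(x)[2]; ch <- dim(x)[3]
  lp <- l %/% p
  a <- array(x[, seq_len(lp * p), , drop = FALSE], c(b, p, lp, ch))
  out <- array(-Inf, c(b, lp, ch))
  idx <- array(1L, c(b, lp, ch))
  for (q in seq_len(p)) {
    v <- array(a[, q, , , drop = FALSE], c(b, lp, ch))
    m <- v > out                       # ties: earliest position wins
    out[m] <- v[m]
    idx[m] <- q
  }
  list(out = out, idx = idx)
}

maxpool_bwd <- function(dout, idx, p, l_in) {
  b <- dim(dout)[1]; lp <- dim(dout)[2]; ch <- dim(dout)[3]
  da <- array(0, c(b, p, lp, ch))
  for (q in seq_len(p)) {
    m <- idx == q
    dq <- array(0, c(b, lp, ch))
    dq[m] <- dout[m]
    da[, q, , ] <- dq
  }
  dx <- array(0, c(b, l_in, ch))
  dx[, seq_len(lp * p), ] <- array(da, c(b, lp * p, ch))
  dx
}

#' Initialise an untrained network
#'
#' He-normal weight initialisation; dimensions are derived from the input
#' length and the configuration. Errors if the input is too short for two
#' valid convolution + pooling blocks.
#'
#' @param input_len Number of input features (50, or 51 with age).
#' @param cfg A [cv_config()].
#' @return A `plr_cnn` model object.
#' @export
cnn_init <- function(input_len, cfg = cv_config()) {
  k <- cfg$kernel_size
  f1 <- cfg$filters[1]; f2 <- cfg$filters[2]
  l1 <- input_len - k + 1
  p1 <- l1 %/% cfg$pool_size
  l2 <- p1 - k + 1
  p2 <- l2 %/% cfg$pool_size
  if (l1 < cfg$pool_size || l2 < cfg$pool_size || p2 < 1) {
    stop("input of length ", input_len,
         " is too short for the configured architecture")
  }
  flat <- p2 * f2
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)),
                                        nr, nc)
  params <- list(
    W1 = he(k, f1, k), b1 = numeric(f1),
    W2 = he(k * f1, f2, k * f1), b2 = numeric(f2),
    W3 = he(flat, cfg$dense_units, flat), b3 = numeric(cfg$dense_units),
    W4 = he(cfg$dense_units, 2L, cfg$dense_units), b4 = numeric(2L)
  )
  structure(
    list(params = params, cfg = cfg,
         dims = list(input_len = input_len, l1 = l1, p1 = p1,
                     l2 = l2, p2 = p2, flat = flat),
         trained = FALSE, history = NULL, best_val_loss = NA_real_),
    class = "plr_cnn"
  )
}

cnn_forward <- function(model, x, train = FALSE) {
  p <- model$params; cfg <- model$cfg; d <- model$dims
  b <- nrow(x)
  x3 <- array(x, c(b, d$input_len, 1L))
  c1 <- im2col(x3, cfg$kernel_size)
  z1 <- sweep(c1 %*% p$W1, 2, p$b1, "+")
  a1 <- array(pmax(z1, 0), c(b, d$l1, cfg$filters[1]))
  m1 <- maxpool_fwd(a1, cfg$pool_size)
  c2 <- im2col(m1$out, cfg$kernel_size)
  z2 <- sweep(c2 %*% p$W2, 2, p$b2, "+")
  a2 <- array(pmax(z2, 0), c(b, d$l2, cfg$filters[2]))
  m2 <- maxpool_fwd(a2, cfg$pool_size)
  flat <- matrix(m2$out, b, d$flat)
  z3 <- sweep(flat %*% p$W3, 2, p$b3, "+")
  a3 <- pmax(z3, 0)
  mask <- NULL
  a3d <- a3
  if (train && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    mask <- matrix(rbinom(length(a3), 1, keep), nrow(a3)) / keep
    a3d <- a3 * mask
  }
  z4 <- sweep(a3d %*% p$W4, 2, p$b4, "+")
  zs <- z4 - apply(z4, 1, max)
  ez <- exp(zs)
  probs <- ez / rowSums(ez)
  list(probs = probs,
       cache = list(c1 = c1, z1 = z1, m1 = m1, c2 = c2, z2 = z2, m2 = m2,
                    flat = flat, z3 = z3, a3d = a3d, mask = mask))
}

cnn_loss_value <- function(probs, y) {
  -mean(rowSums(y * log(probs + 1e-12)))
}

cnn_backward <- function(model, fwd, y) {
  p <- model$params; cfg <- model$cfg; d <- model$dims
  ca <- fwd$cache
  b <- nrow(y)
  dz4 <- (fwd$probs - y) / b
  g_w4 <- t(ca$a3d) %*% dz4
  g_b4 <- colSums(dz4)
  da3d <- dz4 %*% t(p$W4)
  da3 <- if (is.null(ca$mask)) da3d else da3d * ca$mask
  dz3 <- da3 * (ca$z3 > 0)
  g_w3 <- t(ca$flat) %*% dz3
  g_b3 <- colSums(dz3)
  dflat <- dz3 %*% t(p$W3)
  dm2 <- array(dflat, c(b, d$p2, cfg$filters[2]))
  da2 <- maxpool_bwd(dm2, ca$m2$idx, cfg$pool_size, d$l2)
  dz2 <- matrix(da2, b * d$l2, cfg$filters[2]) * (ca$z2 > 0)
  g_w2 <- t(ca$c2) %*% dz2
  g_b2 <- colSums(dz2)
  dc2 <- dz2 %*% t(p$W2)
  dm1 <- col2im_add(dc2, b, d$p1, cfg$filters[1], cfg$kernel_size)
  da1 <- maxpool_bwd(dm1, ca$m1$idx, cfg$pool_size, d$l1)
  dz1 <- matrix(da1, b * d$l1, cfg$filters[1]) * (ca$z1 > 0)
  g_w1 <- t(ca$c1) %*% dz1
  g_b1 <- colSums(dz1)
  list(W1 = g_w1, b1 = g_b1, W2 = g_w2, b2 = g_b2,
       W3 = g_w3, b3 = g_b3, W4 = g_w4, b4 = g_b4)
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the network with Adam and early stopping
#'
#' Minibatch training on categorical cross-entropy. After every epoch the
#' validation loss is evaluated (without dropout); when it fails to improve
#' for `early_stopping_patience` consecutive epochs training halts and the
#' best-validation-loss weights are restored. `max_epochs = 0` returns the
#' freshly initialised (untrained) network, whose accuracy is at chance.
#' Fully reproducible under `seed`.
#'
#' @param x_train,x_val Feature matrices (rows = subjects), already
#'   standardized.
#' @param y_train,y_val One-hot label matrices (columns Control, AMD).
#' @param cfg A [cv_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return A trained `plr_cnn` with `history` (per-epoch validation loss).
#' @export
build_and_train_cnn <- function(x_train, y_train, x_val, y_val,
                                cfg = cv_config(), seed = cfg$seed) {
  stopifnot(nrow(x_train) == nrow(y_train), nrow(x_val) == nrow(y_val))
  if (nrow(x_val) < 1 || nrow(x_train) < 2) {
    stop("configuration error: too few subjects to train with a validation split")
  }
  with_local_seed(seed, {
    model <- cnn_init(ncol(x_train), cfg)
    if (cfg$max_epochs == 0) return(model)
    state <- adam_init(model$params)
    best <- model$params
    best_loss <- Inf
    wait <- 0L
    history <- numeric(0)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(nrow(x_train))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bt in batches) {
        fwd <- cnn_forward(model, x_train[bt, , drop = FALSE], train = TRUE)
        gr <- cnn_backward(model, fwd, y_train[bt, , drop = FALSE])
        upd <- adam_step(model$params, gr, state, cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      vfwd <- cnn_forward(model, x_val, train = FALSE)
      vloss <- cnn_loss_value(vfwd$probs, y_val)
      history <- c(history, vloss)
      if (vloss < best_loss - 1e-6) {
        best_loss <- vloss
        best <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      if (wait >= cfg$early_stopping_patience) break
    }
    model$params <- best
    model$trained <- TRUE
    model$history <- history
    model$best_val_loss <- best_loss
    model
  })
}

#' Predict class probabilities
#'
#' @param object A `plr_cnn`.
#' @param x Feature matrix (standardized with the training statistics).
#' @param ... Unused.
#' @return Matrix of class probabilities, columns `Control`, `AMD`.
#' @export
predict.plr_cnn <- function(object, x, ...) {
  probs <- cnn_forward(object, x, train = FALSE)$probs
  colnames(probs) <- c("Control", "AMD")
  probs
}

#' @export
print.plr_cnn <- function(x, ...) {
  d <- x$dims; cfg <- x$cfg
  cat("<plr_cnn> 1-D convolutional classifier\n")
  cat(sprintf("  input %d -> conv%d(k%d) -> pool%d -> conv%d(k%d) -> pool%d -> dense%d -> dropout %.2f -> softmax 2\n",
              d$input_len, cfg$filters[1], cfg$kernel_size, cfg$pool_size,
              cfg$filters[2], cfg$kernel_size, cfg$pool_size,
              cfg$dense_units, cfg$dropout_rate))
  cat(if (x$trained) {
    sprintf("  trained: %d epochs, best val loss %.4f\n",
            length(x$history), x$best_val_loss)
  } else "  untrained\n")
  invisible(x)
}
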