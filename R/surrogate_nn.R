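# Fingerprint feedforward network: 2 hidden ReLU layers of 100 units,
# dropout p = 0.2 after each hidden layer, Adam (lr 0.01), mean-squared
# error with L2 penalty 0.01, batch 4096, up to 50 epochs with early
# stopping (patience 5) on a random 20% validation split. Predictive
# uncertainty by Monte-Carlo dropout (10 stochastic forward passes).
#
# Implemented directly in base-R matrix code with hand-written
# backpropagation; inverted dropout is used so the p = 0 limit is exact
# deterministic inference.

nn_init <- function(dims) {
  # He initialization for ReLU stacks
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass; returns activations needed for backprop.
# dropout masks: list per hidden layer (NULL = no dropout), inverted scaling.
nn_forward <- function(par, X, dropout = 0, sample_masks = FALSE) {
  L <- length(par$W)
  A <- X
  cache <- list(A0 = X, Z = vector("list", L), A = vector("list", L),
                M = vector("list", L))
  for (l in seq_len(L)) {
    Z <- sweep(A %*% par$W[[l]], 2, par$b[[l]], `+`)
    if (l < L) {
      A <- pmax(Z, 0)
      if (sample_masks && dropout > 0) {
        M <- matrix(stats::rbinom(length(A), 1, 1 - dropout) / (1 - dropout),
                    nrow(A), ncol(A))
        A <- A * M
        cache$M[[l]] <- M
      }
    } else {
      A <- Z
    }
    cache$Z[[l]] <- Z
    cache$A[[l]] <- A
  }
  cache$out <- as.numeric(A)
  cache
}

# Gradient of mean((out - y)^2)/2-free form: we use full MSE (mean of squares).
nn_backward <- function(par, cache, y, l2 = 0) {
  L <- length(par$W)
  n <- length(y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(2 * (cache$out - y) / n, ncol = 1)
  for (l in rev(seq_len(L))) {
    A_prev <- if (l == 1) cache$A0 else cache$A[[l - 1]]
    gW[[l]] <- crossprod(A_prev, delta) + 2 * l2 * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(par$W[[l]])
      if (!is.null(cache$M[[l - 1]])) delta <- delta * cache$M[[l - 1]]
      delta <- delta * (cache$Z[[l - 1]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(par) {
  zero <- function(x) lapply(x, function(p) p * 0)
  list(mW = zero(par$W), vW = zero(par$W), mb = zero(par$b), vb = zero(par$b),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (l in seq_along(par$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grad$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    par$W[[l]] <- par$W[[l]] -
      lr * (state$mW[[l]] / corr1) / (sqrt(state$vW[[l]] / corr2) + eps)
  }
  for (l in seq_along(par$b)) {
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grad$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    par$b[[l]] <- par$b[[l]] -
      lr * (state$mb[[l]] / corr1) / (sqrt(state$vb[[l]] / corr2) + eps)
  }
  list(par = par, state = state)
}

train_nn <- function(spec, X, y, seed, prev_model = NULL) {
  hp <- spec$hyperparameters
  set.seed(seed)
  scaler <- target_scaler(y)
  ys <- (y - scaler$mu) / scaler$sd
  n <- nrow(X)

  online <- spec$retrain_mode == "online" && !is.null(prev_model)
  par <- if (online) prev_model$par else nn_init(c(ncol(X), hp$hidden, 1L))

  # early-stopping split; degenerate targets (or val_frac = 0) fall back to
  # fixed-epoch training
  use_val <- hp$val_frac > 0 && length(unique(y)) >= 2 && n >= 5
  if (!use_val && length(unique(y)) < 2)
    warning("fewer than 2 distinct target values: training without early stopping")
  if (use_val) {
    val_idx <- sample.int(n, max(1L, round(hp$val_frac * n)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0L) { use_val <- FALSE; tr_idx <- seq_len(n) }
  } else tr_idx <- seq_len(n)

  opt <- adam_init(par)
  best <- list(par = par, val = Inf, since = 0L)
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / hp$batch_size))
    for (bi in batches) {
      cache <- nn_forward(par, X[bi, , drop = FALSE], dropout = hp$dropout,
                          sample_masks = TRUE)
      grad <- nn_backward(par, cache, ys[bi], l2 = hp$l2)
      upd <- adam_step(par, grad, opt, lr = hp$lr)
      par <- upd$par; opt <- upd$state
    }
    if (use_val) {
      pv <- nn_forward(par, X[val_idx, , drop = FALSE])$out
      val <- mean((pv - ys[val_idx])^2)
      if (val < best$val - 1e-12) {
        best <- list(par = par, val = val, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= hp$patience) break
      }
    }
  }
  if (use_val) par <- best$par
  list(par = par, scaler = scaler)
}

#' @export
predict_surrogate.surrogate_nn <- function(model, pool) {
  hp <- model$spec$hyperparameters
  X <- pool$fingerprints
  sc <- model$scaler
  if (model$spec$uncertainty == "none") {
    mu <- nn_forward(model$par, X)$out * sc$sd + sc$mu
    return(check_prediction(list(mean = mu, variance = NULL), pool$size))
  }
  # MC dropout: mean and variance across stochastic forward passes
  passes <- matrix(0, nrow(X), hp$mc_passes)
  for (p in seq_len(hp$mc_passes)) {
    passes[, p] <- nn_forward(model$par, X, dropout = hp$dropout,
                              sample_masks = hp$dropout > 0)$out
  }
  mu_s <- rowMeans(passes)
  var_s <- rowMeans(passes^2) - mu_s^2
  var_s[var_s < 0] <- 0
  check_prediction(list(mean = mu_s * sc$sd + sc$mu,
                        variance = var_s * sc$sd^2), pool$size)
}
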