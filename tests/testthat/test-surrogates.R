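# Surrogate models: RF ensemble variance, NN with MC-dropout, MPN with MVE.

test_that("RF predicts the constant for constant targets", {
  pool <- tiny_pool()
  m <- train_surrogate(surrogate_spec("rf"), pool, 1:6, rep(4.2, 6), seed = 1)
  p <- predict_surrogate(m, pool)
  expect_equal(p$mean, rep(4.2, pool$size), tolerance = 1e-12)
  expect_equal(p$variance, rep(0, pool$size), tolerance = 1e-12)
})

test_that("a single-tree forest has zero variance on its own training points", {
  pool <- tiny_pool()
  y <- seq_len(pool$size)
  m <- train_surrogate(surrogate_spec("rf", num_trees = 1L), pool,
                       seq_len(pool$size), y, seed = 2)
  p <- predict_surrogate(m, pool)
  expect_equal(p$variance, rep(0, pool$size), tolerance = 1e-12)
})

test_that("RF variance equals the across-tree prediction variance", {
  fx <- cached_fixture(n = 100, noise_sigma = 0.3)
  pool <- fx$pool
  y <- -fx$raw_scores
  m <- train_surrogate(surrogate_spec("rf"), pool, 1:40, y[1:40], seed = 3)
  pred <- predict(m$fit, data = as.data.frame(pool$fingerprints),
                  predict.all = TRUE, num.threads = 1)$predictions
  p <- predict_surrogate(m, pool)
  expect_equal(p$mean, rowMeans(pred))
  expect_equal(p$variance, apply(pred, 1, function(r) mean((r - mean(r))^2)),
               tolerance = 1e-10)
})

test_that("NN inference without dropout is deterministic; MC passes with p=0 have zero variance", {
  fx <- cached_fixture(n = 100, noise_sigma = 0.3)
  pool <- fx$pool
  y <- -fx$raw_scores
  m <- train_surrogate(surrogate_spec("nn", uncertainty = "none", epochs = 5L),
                       pool, 1:50, y[1:50], seed = 4)
  p1 <- predict_surrogate(m, pool)
  p2 <- predict_surrogate(m, pool)
  expect_identical(p1$mean, p2$mean)
  expect_null(p1$variance)

  m0 <- train_surrogate(surrogate_spec("nn", dropout = 0, epochs = 5L),
                        pool, 1:50, y[1:50], seed = 4)
  p0 <- predict_surrogate(m0, pool)
  expect_equal(p0$variance, rep(0, pool$size), tolerance = 1e-20)
})

test_that("10-pass MC-dropout agrees with a large-pass estimate within MC error", {
  fx <- cached_fixture(n = 60, noise_sigma = 0.3)
  pool <- fx$pool
  y <- -fx$raw_scores
  m <- train_surrogate(surrogate_spec("nn", hidden = c(16L, 16L), epochs = 10L),
                       pool, 1:30, y[1:30], seed = 6)
  ns <- asNamespace("screenbo")
  hp <- m$spec$hyperparameters
  sc <- m$scaler
  big <- 4000L
  X <- pool$fingerprints
  set.seed(100)
  passes <- matrix(0, nrow(X), big)
  for (p in seq_len(big))
    passes[, p] <- ns$nn_forward(m$par, X, dropout = hp$dropout,
                                 sample_masks = TRUE)$out
  ref_mean <- rowMeans(passes) * sc$sd + sc$mu
  per_pass_sd <- apply(passes, 1, sd) * sc$sd
  set.seed(101)
  p10 <- predict_surrogate(m, pool)
  # 10-pass mean is within ~4 standard errors of the 4000-pass mean
  se10 <- per_pass_sd / sqrt(10)
  expect_true(all(abs(p10$mean - ref_mean) < 4.5 * se10 + 1e-9))
  expect_true(all(p10$variance >= 0))
})

test_that("RF and NN recover a linear fingerprint landscape from a 10% split", {
  fx <- cached_fixture(n = 1000, noise_sigma = 0.1)
  pool <- fx$pool
  y <- -fx$raw_scores
  tr <- 1:100
  te <- setdiff(seq_len(pool$size), tr)
  rho_for <- function(spec, tr_idx) {
    m <- train_surrogate(spec, pool, tr_idx, y[tr_idx], seed = 11)
    p <- predict_surrogate(m, pool)
    te_idx <- setdiff(seq_len(pool$size), tr_idx)
    cor(p$mean[te_idx], y[te_idx], method = "spearman")
  }
  expect_gt(rho_for(surrogate_spec("nn", uncertainty = "none"), tr), 0.7)
  # the depth-capped forest is a coarser regressor at this training size
  rho_rf10 <- rho_for(surrogate_spec("rf"), tr)
  expect_gt(rho_rf10, 0.55)
  # held-out correlation improves as the training fraction grows
  expect_gt(rho_for(surrogate_spec("rf"), 1:500), rho_rf10)
})

test_that("training is reproducible for a fixed seed", {
  fx <- cached_fixture(n = 100, noise_sigma = 0.3)
  pool <- fx$pool
  y <- -fx$raw_scores
  for (spec in list(surrogate_spec("rf"),
                    surrogate_spec("nn", epochs = 3L),
                    surrogate_spec("mpn", hidden = 16L, epochs = 2L))) {
    m1 <- train_surrogate(spec, pool, 1:40, y[1:40], seed = 9)
    m2 <- train_surrogate(spec, pool, 1:40, y[1:40], seed = 9)
    withr::with_seed(1, p1 <- predict_surrogate(m1, pool))
    withr::with_seed(1, p2 <- predict_surrogate(m2, pool))
    expect_equal(p1$mean, p2$mean, tolerance = 1e-12)
  }
})

test_that("degenerate targets fall back to no-early-stopping training with a warning", {
  pool <- tiny_pool()
  expect_warning(
    m <- train_surrogate(surrogate_spec("nn", epochs = 2L), pool, 1:6,
                         rep(1, 6), seed = 1),
    "distinct target values")
  p <- predict_surrogate(m, pool)
  expect_true(all(is.finite(p$mean)))
})

test_that("mve_loss evaluates the Gaussian negative log likelihood", {
  expect_equal(mve_loss(0, 1, 0), 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(mve_loss(0, 2, 1), 0.5 * log(4 * pi) + 0.25, tolerance = 1e-12)
  # minimized over variance at variance = squared residual
  resid2 <- (1.3 - 0.4)^2
  vgrid <- seq(0.05, 5, by = 0.001)
  lvals <- vapply(vgrid, function(v) mve_loss(0.4, v, 1.3), numeric(1))
  expect_equal(vgrid[which.min(lvals)], resid2, tolerance = 2e-3)
  expect_error(mve_loss(0, 0, 1), "positive")
  # batch loss is the mean over examples
  expect_equal(mve_loss(c(0, 0), c(1, 2), c(0, 1)),
               mean(c(0.5 * log(2 * pi), 0.5 * log(4 * pi) + 0.25)))
})

test_that("MPN analytic gradients match finite differences", {
  ns <- asNamespace("screenbo")
  graphs <- ns$parse_molecules(c("CCO", "CC(C)N", "c1ccccc1", "C"))
  bg <- ns$mpn_batch(graphs)
  set.seed(21)
  y <- c(0.5, -1, 2, 0)
  for (mve in c(FALSE, TRUE)) {
    par <- ns$mpn_init(6L, if (mve) 2L else 1L)
    cache <- ns$mpn_forward(par, bg, 3L)
    lg <- ns$mpn_loss_grad(cache$out, y, mve)
    g <- ns$mpn_backward(par, bg, cache, lg$dOut, 3L)
    eps <- 1e-6
    for (nm in c("Wi", "Wh", "Wo", "W1", "W2", "b1", "b2")) {
      idx <- sample(length(par[[nm]]), min(4, length(par[[nm]])))
      num <- vapply(idx, function(i) {
        pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
        lp <- ns$mpn_loss_grad(ns$mpn_forward(pp, bg, 3L)$out, y, mve)$loss
        pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
        lm <- ns$mpn_loss_grad(ns$mpn_forward(pm, bg, 3L)$out, y, mve)$loss
        (lp - lm) / (2 * eps)
      }, numeric(1))
      expect_equal(g[[nm]][idx], num, tolerance = 1e-4,
                   info = paste(nm, "mve =", mve))
    }
  }
})

test_that("MPN trains, yields positive variance, and fits improve with epochs", {
  fx <- cached_fixture(n = 120, noise_sigma = 0.1)
  pool <- fx$pool
  y <- -fx$raw_scores
  tr <- 1:60
  short <- train_surrogate(
    surrogate_spec("mpn", hidden = 32L, epochs = 2L, val_frac = 0,
                   lr_max = 5e-3, lr_final = 5e-4),
    pool, tr, y[tr], seed = 13)
  long <- train_surrogate(
    surrogate_spec("mpn", hidden = 32L, epochs = 60L, val_frac = 0,
                   lr_max = 5e-3, lr_final = 5e-4),
    pool, tr, y[tr], seed = 13)
  ps <- predict_surrogate(short, pool)
  pl <- predict_surrogate(long, pool)
  expect_true(all(pl$variance > 0))
  rmse_s <- sqrt(mean((ps$mean[tr] - y[tr])^2))
  rmse_l <- sqrt(mean((pl$mean[tr] - y[tr])^2))
  expect_lt(rmse_l, rmse_s)
  expect_gt(cor(pl$mean[tr], y[tr], method = "spearman"), 0.3)
})

test_that("surrogate checkpoints round-trip through save/load", {
  fx <- cached_fixture(n = 60, noise_sigma = 0.3)
  pool <- fx$pool
  y <- -fx$raw_scores
  m <- train_surrogate(surrogate_spec("rf"), pool, 1:30, y[1:30], seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_surrogate(m, f)
  m2 <- load_surrogate(f)
  expect_equal(predict_surrogate(m2, pool)$mean,
               predict_surrogate(m, pool)$mean)
})

test_that("online retraining continues from the previous model", {
  fx <- cached_fixture(n = 100, noise_sigma = 0.3)
  pool <- fx$pool
  y <- -fx$raw_scores
  spec <- surrogate_spec("nn", retrain_mode = "online", epochs = 3L)
  m1 <- train_surrogate(spec, pool, 1:30, y[1:30], seed = 4)
  m2 <- train_surrogate(spec, pool, 31:40, y[31:40], seed = 5, prev_model = m1)
  expect_false(identical(m1$par$W[[1]], m2$par$W[[1]]))
  p <- predict_surrogate(m2, pool)
  expect_true(all(is.finite(p$mean)))
})
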