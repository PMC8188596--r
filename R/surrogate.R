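# Surrogate models: regressors f-hat trained on acquired (structure, score)
# pairs, predicting a mean and (architecture permitting) a variance for
# every pool member.
#
# Architectures: RF (fingerprints; ensemble variance across trees),
# NN (fingerprints; MC-dropout variance), MPN (molecular graph; MVE
# mean-variance head). All follow the maximization convention of the
# objective module.

#' Specify a surrogate model
#'
#' @param architecture `"rf"`, `"nn"` or `"mpn"`.
#' @param uncertainty uncertainty estimator; the default pairs each
#'   architecture with its native method (`rf` -> `"ensemble"` across-tree
#'   variance, `nn` -> `"mc-dropout"`, `mpn` -> `"mve"`). `"none"` disables
#'   variance output (sufficient for greedy acquisition).
#' @param retrain_mode `"full"` (default; reinitialize and train on all
#'   acquired data each iteration) or `"online"` (continue training the
#'   previous model on the newly acquired batch only).
#' @param ... architecture hyperparameters overriding the defaults:
#'   \describe{
#'     \item{rf}{`num_trees` (100), `rf_depth` (8)}
#'     \item{nn}{`hidden` (c(100, 100)), `dropout` (0.2), `lr` (0.01),
#'       `l2` (0.01), `batch_size` (4096), `epochs` (50), `patience` (5),
#'       `val_frac` (0.2), `mc_passes` (10)}
#'     \item{mpn}{`hidden` (300), `depth` (3), `lr_init` (1e-4),
#'       `lr_max` (1e-3), `lr_final` (1e-4), `batch_size` (50),
#'       `epochs` (50), `patience` (10), `val_frac` (0.2)}
#'   }
#' @return a `surrogate_spec`.
#' @export
surrogate_spec <- function(architecture = c("rf", "nn", "mpn"),
                           uncertainty = NULL,
                           retrain_mode = c("full", "online"), ...) {
  architecture <- match.arg(architecture)
  retrain_mode <- match.arg(retrain_mode)
  native <- c(rf = "ensemble", nn = "mc-dropout", mpn = "mve")
  uncertainty <- uncertainty %||% native[[architecture]]
  if (!uncertainty %in% c("none", native[[architecture]]))
    stop("uncertainty method '", uncertainty,
         "' is not available for architecture '", architecture, "'")
  defaults <- switch(architecture,
    rf  = list(num_trees = 100L, rf_depth = 8L),
    nn  = list(hidden = c(100L, 100L), dropout = 0.2, lr = 0.01, l2 = 0.01,
               batch_size = 4096L, epochs = 50L, patience = 5L,
               val_frac = 0.2, mc_passes = 10L),
    mpn = list(hidden = 300L, depth = 3L, lr_init = 1e-4, lr_max = 1e-3,
               lr_final = 1e-4, batch_size = 50L, epochs = 50L,
               patience = 10L, val_frac = 0.2))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", architecture, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  structure(list(architecture = architecture, uncertainty = uncertainty,
                 retrain_mode = retrain_mode, hyperparameters = defaults),
            class = "surrogate_spec")
}

#' Train a surrogate on acquired data
#'
#' @param spec a [surrogate_spec()].
#' @param pool the `molecule_pool` (provides fingerprints/graphs).
#' @param indices pool indices of the training molecules (scored acquisitions
#'   only; molecules whose evaluation returned no value must not be passed).
#' @param targets objective values (maximization convention), same length as
#'   `indices`.
#' @param seed integer seed; training is reproducible given the seed.
#' @param prev_model previous model for `retrain_mode = "online"`.
#' @return a fitted `surrogate_model`.
#' @export
train_surrogate <- function(spec, pool, indices, targets, seed = 0L,
                            prev_model = NULL) {
  stopifnot(inherits(spec, "surrogate_spec"),
            length(indices) == length(targets), length(indices) >= 1,
            all(is.finite(targets)))
  model <- switch(spec$architecture,
    rf  = train_rf(spec, pool$fingerprints[indices, , drop = FALSE],
                   targets, seed),
    nn  = train_nn(spec, pool$fingerprints[indices, , drop = FALSE],
                   targets, seed, prev_model),
    mpn = train_mpn(spec, pool$graphs[indices], targets, seed, prev_model))
  model$spec <- spec
  class(model) <- c(paste0("surrogate_", spec$architecture), "surrogate_model")
  model
}

#' Predict mean (and variance) for every pool member
#'
#' Full-pool inference: one mean per candidate, aligned with pool indices,
#' including already-acquired members. Variance is returned when the spec's
#' uncertainty method provides it, otherwise `NULL`.
#'
#' @param model a `surrogate_model`.
#' @param pool a `molecule_pool`.
#' @return list with `mean` (numeric, length `pool$size`) and `variance`
#'   (numeric or `NULL`). Variances are nonnegative; all values finite.
#' @export
predict_surrogate <- function(model, pool) {
  UseMethod("predict_surrogate")
}

#' @export
predict_surrogate.surrogate_rf <- function(model, pool) {
  pred <- predict(model$fit, data = as.data.frame(pool$fingerprints),
                  predict.all = TRUE, num.threads = 1)$predictions
  out <- list(mean = rowMeans(pred), variance = NULL)
  if (model$spec$uncertainty == "ensemble") {
    # across-tree population variance of the ensemble's predictions
    out$variance <- rowMeans(pred^2) - rowMeans(pred)^2
    out$variance[out$variance < 0] <- 0  # numerical floor
  }
  check_prediction(out, pool$size)
}

train_rf <- function(spec, X, y, seed) {
  hp <- spec$hyperparameters
  df <- as.data.frame(X)
  df$.y <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = hp$num_trees, max.depth = hp$rf_depth,
    seed = seed, num.threads = 1, verbose = FALSE)
  list(fit = fit)
}

check_prediction <- function(pred, n) {
  stopifnot(length(pred$mean) == n, all(is.finite(pred$mean)))
  if (!is.null(pred$variance))
    stopifnot(length(pred$variance) == n, all(is.finite(pred$variance)),
              all(pred$variance >= 0))
  pred
}

# Standardize targets (NN/MPN) on the current training set; predictions are
# un-standardized on the way out. Degenerate spread falls back to scale 1.
target_scaler <- function(y) {
  mu <- mean(y)
  sd <- stats::sd(y)
  if (!is.finite(sd) || sd == 0) sd <- 1
  list(mu = mu, sd = sd)
}

#' Save / load a surrogate model checkpoint
#'
#' Serialization so a run can resume; the spec (all hyperparameters) travels
#' with the weights.
#'
#' @param model a `surrogate_model`.
#' @param path file path.
#' @return `load_surrogate` returns the model.
#' @export
save_surrogate <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) readRDS(path)
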