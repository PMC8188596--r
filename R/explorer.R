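# Explorer: the batched Bayesian-optimization loop.
#
#   initialize with a random batch -> repeat { retrain surrogate on all
#   scored data; predict over the whole pool; acquire the top-b untested
#   candidates by acquisition utility; evaluate them } until a fixed budget
#   is exhausted, the top-k average converges, or the pool runs out.

#' Explorer configuration
#'
#' @param init_size initial random batch: fraction of the pool (values < 1)
#'   or an absolute count. Fractions are converted with a ceiling and a
#'   floor of one molecule, so 1% of 10,560 is 106 and 1% of 50,240 is 503.
#' @param batch_size exploration batch b, fraction or count (same rounding).
#' @param max_iterations number of exploration batches after initialization
#'   (default 5).
#' @param k size of the tracked top-k (default 100).
#' @param stopping `"fixed"` (run `max_iterations` batches) or `"converged"`
#'   (stop early once the top-k average stops improving, see
#'   [check_convergence()]; `max_iterations` still caps the run).
#' @param convergence_threshold fractional-difference threshold (default 0.01).
#' @param convergence_window number of prior iterations in the rolling
#'   average (default 3).
#' @param signed_convergence if `TRUE`, use the signed improvement rather
#'   than its absolute value in the convergence test.
#' @param surrogate a [surrogate_spec()]; may be `NULL` for
#'   `metric = "random"`, which never consults the model.
#' @param acquisition an [acquisition_config()].
#' @param seed master seed; every random draw in the run derives from it.
#' @return an `explorer_config`.
#' @export
explorer_config <- function(init_size = 0.01, batch_size = 0.01,
                            max_iterations = 5L, k = 100L,
                            stopping = c("fixed", "converged"),
                            convergence_threshold = 0.01,
                            convergence_window = 3L,
                            signed_convergence = FALSE,
                            surrogate = surrogate_spec("rf"),
                            acquisition = acquisition_config("greedy"),
                            seed = 0L) {
  stopping <- match.arg(stopping)
  stopifnot(convergence_threshold > 0, convergence_window >= 1,
            max_iterations >= 0, k >= 1)
  if (acquisition$metric != "random" && is.null(surrogate))
    stop("a surrogate_spec is required for metric '", acquisition$metric, "'")
  structure(list(init_size = init_size, batch_size = batch_size,
                 max_iterations = as.integer(max_iterations), k = as.integer(k),
                 stopping = stopping,
                 convergence_threshold = convergence_threshold,
                 convergence_window = as.integer(convergence_window),
                 signed_convergence = isTRUE(signed_convergence),
                 surrogate = surrogate, acquisition = acquisition,
                 seed = as.integer(seed)),
            class = "explorer_config")
}

#' Initialize an exploration run with a random batch
#'
#' Draws `init_size` molecules uniformly without replacement (deterministic
#' per seed) and evaluates them against the objective. Molecules whose
#' evaluation returns no value (failed docks) consume budget but contribute
#' no training data.
#'
#' @param pool a `molecule_pool`.
#' @param objective a `lookup_table`.
#' @param config an [explorer_config()].
#' @return an `explorer_state`: list with `tested` (indices in acquisition
#'   order), `iteration_of` (iteration each tested molecule was acquired,
#'   0 = initialization), `scores` (objective values aligned with `tested`,
#'   `NA` = missing), `iteration`, `topk_history`, `log`.
#' @export
initialize_explorer <- function(pool, objective, config) {
  n_init <- frac_to_count(config$init_size, pool$size)
  if (n_init > pool$size) stop("init_size exceeds pool size")
  idx <- withr_seed(derive_seed(config$seed, 0L), sample.int(pool$size, n_init))
  res <- evaluate_batch(objective, pool$smiles[idx])
  state <- list(tested = idx,
                iteration_of = rep(0L, n_init),
                scores = res$objective_value,
                iteration = 0L,
                topk_history = numeric(0),
                log = NULL)
  state <- log_iteration(state, config)
  state
}

# append the current top-k average and a log row
log_iteration <- function(state, config) {
  scored <- state$scores[!is.na(state$scores)]
  k_eff <- min(config$k, length(scored))
  topk_avg <- if (k_eff >= 1) mean(sort(scored, decreasing = TRUE)[seq_len(k_eff)])
              else NA_real_
  state$topk_history <- c(state$topk_history, topk_avg)
  row <- data.frame(iteration = state$iteration,
                    n_tested = length(state$tested),
                    n_scored = length(scored),
                    top_k_average = topk_avg,
                    best_score = if (length(scored)) max(scored) else NA_real_)
  state$log <- rbind(state$log, row)
  state
}

#' Run one train/predict/acquire/evaluate iteration
#'
#' Retrains the surrogate on all scored acquisitions (or continues training
#' on the new batch in online mode), predicts over the full pool, selects
#' the top-b untested candidates by acquisition utility, and evaluates them.
#' With `metric = "random"` the surrogate step is skipped entirely: the
#' random baseline runs inside the same loop with identical budget
#' accounting.
#'
#' @param state an `explorer_state`.
#' @param pool,objective,config as in [initialize_explorer()].
#' @param model_env optional environment carrying the previous model (for
#'   online retraining); updated in place.
#' @return updated `explorer_state`.
#' @export
run_iteration <- function(state, pool, objective, config, model_env = NULL) {
  if (length(state$tested) >= pool$size)
    stop("untested pool exhausted")
  iter <- state$iteration + 1L
  set.seed(derive_seed(config$seed, iter))
  b <- frac_to_count(config$batch_size, pool$size)

  if (config$acquisition$metric == "random") {
    util <- stats::runif(pool$size)
    incumbent <- NULL
  } else {
    scored_mask <- !is.na(state$scores)
    train_idx <- state$tested[scored_mask]
    train_y <- state$scores[scored_mask]
    if (length(train_y) == 0L)
      stop("no scored molecules available for surrogate training")
    prev <- if (!is.null(model_env)) model_env$model else NULL
    new_idx <- state$iteration_of == state$iteration & scored_mask
    model <- if (config$surrogate$retrain_mode == "online" && !is.null(prev)) {
      train_surrogate(config$surrogate, pool,
                      state$tested[new_idx], state$scores[new_idx],
                      seed = derive_seed(config$seed, iter), prev_model = prev)
    } else {
      train_surrogate(config$surrogate, pool, train_idx, train_y,
                      seed = derive_seed(config$seed, iter))
    }
    if (!is.null(model_env)) model_env$model <- model
    pred <- predict_surrogate(model, pool)
    incumbent <- max(train_y)
    util <- acquisition_utility(config$acquisition, pred$mean, pred$variance,
                                incumbent = incumbent)
  }
  batch_idx <- select_batch(util, tested = state$tested, b = b)
  res <- evaluate_batch(objective, pool$smiles[batch_idx])

  state$tested <- c(state$tested, batch_idx)
  state$iteration_of <- c(state$iteration_of, rep(iter, length(batch_idx)))
  state$scores <- c(state$scores, res$objective_value)
  state$iteration <- iter
  log_iteration(state, config)
}

#' Convergence test on the top-k average trajectory
#'
#' Converged when the fractional difference between the current top-k
#' average and the rolling mean of the previous `window` iterations'
#' averages falls below `threshold`. Returns `FALSE` while fewer than
#' `window` prior iterations exist. If the rolling mean is exactly zero the
#' absolute difference is compared instead.
#'
#' @param topk_history numeric vector of per-iteration top-k averages; the
#'   last entry is the current iteration unless `current` is given.
#' @param threshold fractional threshold (default 0.01).
#' @param window number of prior iterations averaged (default 3).
#' @param current optionally, the current value (then all of `topk_history`
#'   counts as prior iterations).
#' @param signed compare the signed improvement instead of its magnitude.
#' @return logical.
#' @export
check_convergence <- function(topk_history, threshold = 0.01, window = 3L,
                              current = NULL, signed = FALSE) {
  if (is.null(current)) {
    if (length(topk_history) < window + 1) return(FALSE)
    current <- topk_history[length(topk_history)]
    prior <- topk_history[-length(topk_history)]
  } else {
    prior <- topk_history
  }
  if (length(prior) < window) return(FALSE)
  roll <- mean(prior[(length(prior) - window + 1):length(prior)])
  diff <- current - roll
  if (!signed) diff <- abs(diff)
  if (roll == 0) return(diff < threshold)
  (diff / abs(roll)) < threshold
}

#' Run a full exploration campaign
#'
#' Executes [initialize_explorer()] followed by iterations until the fixed
#' budget is spent, the convergence criterion fires, or the pool is
#' exhausted, then assembles the run report.
#'
#' @inheritParams initialize_explorer
#' @param checkpoint_dir optional directory; the state is saved there after
#'   every iteration so an interrupted run can resume.
#' @return an `explorer_report`: list with `top_k` (data.frame of the best k
#'   evaluated molecules: smiles, raw_score, objective_value,
#'   iteration_acquired), `explored` (full acquisition trace), `log`
#'   (per-iteration statistics), `converged`, and the resolved `config`.
#' @export
run_explorer <- function(pool, objective, config, checkpoint_dir = NULL) {
  state <- initialize_explorer(pool, objective, config)
  model_env <- new.env(parent = emptyenv())
  converged <- FALSE
  while (state$iteration < config$max_iterations &&
         length(state$tested) < pool$size) {
    state <- run_iteration(state, pool, objective, config, model_env)
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(state, file.path(checkpoint_dir,
                               sprintf("state_iter%03d.rds", state$iteration)))
    }
    if (config$stopping == "converged" &&
        check_convergence(state$topk_history,
                          threshold = config$convergence_threshold,
                          window = config$convergence_window,
                          signed = config$signed_convergence)) {
      converged <- TRUE
      break
    }
  }
  explorer_report(state, pool, objective, config, converged)
}

explorer_report <- function(state, pool, objective, config, converged) {
  sign <- if (objective$minimize) -1 else 1
  explored <- data.frame(
    smiles = pool$smiles[state$tested],
    raw_score = sign * state$scores,
    objective_value = state$scores,
    iteration_acquired = state$iteration_of,
    stringsAsFactors = FALSE)
  scored <- explored[!is.na(explored$objective_value), , drop = FALSE]
  ord <- order(-scored$objective_value, scored$smiles)
  top_k <- scored[ord[seq_len(min(config$k, nrow(scored)))], , drop = FALSE]
  rownames(top_k) <- NULL
  structure(list(top_k = top_k, explored = explored, log = state$log,
                 topk_history = state$topk_history, converged = converged,
                 config = config),
            class = "explorer_report")
}

#' @export
print.explorer_report <- function(x, ...) {
  cat("explorer_report:", nrow(x$explored), "molecules tested in",
      x$log$iteration[nrow(x$log)], "iterations",
      if (x$converged) "(converged)" else "(fixed budget)", "\n")
  cat(sprintf("  best objective %.4f; top-%d average %.4f\n",
              max(x$top_k$objective_value), nrow(x$top_k),
              mean(x$top_k$objective_value)))
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `explored.csv` (smiles, score, iteration acquired), `log.csv`
#' (per-iteration statistics), `top_k.csv`, and `config.yaml` (the resolved
#' run configuration) into `dir`.
#'
#' @param report an `explorer_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$explored, file.path(dir, "explored.csv"),
                   row.names = FALSE)
  utils::write.csv(report$log, file.path(dir, "log.csv"), row.names = FALSE)
  utils::write.csv(report$top_k, file.path(dir, "top_k.csv"), row.names = FALSE)
  cfg <- report$config
  cfg$surrogate <- unclass(cfg$surrogate)
  cfg$acquisition <- unclass(cfg$acquisition)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
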