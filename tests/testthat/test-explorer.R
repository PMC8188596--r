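# The batched optimization loop: initialization counts, budget accounting,
# perfect-model limit, convergence, determinism, failed-dock handling.

test_that("fractional sizes convert to the published batch counts", {
  expect_equal(frac_to_count(0.01, 10560), 106L)
  expect_equal(frac_to_count(0.01, 50240), 503L)
  expect_equal(frac_to_count(0.01, 2141514), 21416L)
  expect_equal(frac_to_count(0.004, 2100000), 8400L)
  expect_equal(frac_to_count(0.0001, 100), 1L)  # floor of one molecule
  expect_equal(frac_to_count(25, 100), 25L)     # absolute counts pass through
})

test_that("initialization is uniform, seeded, and deterministic", {
  fx <- cached_fixture(n = 100, noise_sigma = 0.3)
  cfg <- explorer_config(init_size = 0.1, batch_size = 0.1, k = 10, seed = 42)
  s1 <- initialize_explorer(fx$pool, fx$lookup, cfg)
  s2 <- initialize_explorer(fx$pool, fx$lookup, cfg)
  expect_identical(s1$tested, s2$tested)
  expect_length(s1$tested, 10L)
  expect_equal(s1$iteration, 0L)
  expect_length(s1$topk_history, 1L)
  s3 <- initialize_explorer(fx$pool, fx$lookup,
                            explorer_config(init_size = 0.1, batch_size = 0.1,
                                            k = 10, seed = 43))
  expect_false(identical(s1$tested, s3$tested))
})

test_that("an oracle surrogate with greedy acquisition selects the true top-b", {
  fx <- cached_fixture(n = 100, noise_sigma = 0.3)
  pool <- fx$pool
  oracle <- oracle_surrogate(fx$lookup)
  pred <- predict_surrogate(oracle, pool)
  expect_equal(pred$variance, rep(0, pool$size))
  tested <- 1:20
  util <- acquisition_utility(acquisition_config("greedy"), pred$mean)
  sel <- select_batch(util, tested = tested, b = 5)
  truth_order <- setdiff(order(-pred$mean), tested)[1:5]
  expect_setequal(sel, truth_order)
  # UCB with zero variance gives the identical batch
  sel_ucb <- select_batch(
    acquisition_utility(acquisition_config("ucb"), pred$mean, pred$variance),
    tested = tested, b = 5)
  expect_setequal(sel_ucb, sel)
})

test_that("budget accounting: n init + T batches, no molecule evaluated twice", {
  fx <- cached_fixture(n = 200, noise_sigma = 0.3)
  cfg <- explorer_config(init_size = 0.05, batch_size = 0.05,
                         max_iterations = 5, k = 20,
                         surrogate = surrogate_spec("rf"),
                         acquisition = acquisition_config("greedy"), seed = 2)
  rep <- run_explorer(fx$pool, fx$lookup, cfg)
  expect_equal(nrow(rep$explored), 60L)  # 10 + 5 * 10
  expect_equal(anyDuplicated(rep$explored$smiles), 0L)
  expect_equal(unname(table(rep$explored$iteration_acquired)),
               rep(10L, 6L), ignore_attr = TRUE)
  # top-k history never decreases under the maximization convention
  expect_true(all(diff(rep$topk_history) >= -1e-12))
})

test_that("single-iteration mode tests exactly init + batch molecules", {
  fx <- cached_fixture(n = 200, noise_sigma = 0.3)
  cfg <- explorer_config(init_size = 20, batch_size = 30, max_iterations = 1,
                         k = 20, surrogate = surrogate_spec("rf"),
                         acquisition = acquisition_config("greedy"), seed = 3)
  rep <- run_explorer(fx$pool, fx$lookup, cfg)
  expect_equal(nrow(rep$explored), 50L)
  expect_equal(sum(rep$explored$iteration_acquired == 1), 30L)
})

test_that("max_iterations = 0 yields the pure random baseline at init budget", {
  fx <- cached_fixture(n = 100, noise_sigma = 0.3)
  cfg <- explorer_config(init_size = 30, batch_size = 10, max_iterations = 0,
                         k = 10, surrogate = NULL,
                         acquisition = acquisition_config("random"), seed = 4)
  rep <- run_explorer(fx$pool, fx$lookup, cfg)
  expect_equal(nrow(rep$explored), 30L)
  expect_true(all(rep$explored$iteration_acquired == 0))
})

test_that("fixed-seed end-to-end runs are identical, across all metrics", {
  fx <- cached_fixture(n = 120, noise_sigma = 0.3)
  for (metric in c("greedy", "ucb", "ts", "ei", "pi", "random")) {
    cfg <- explorer_config(init_size = 0.1, batch_size = 0.1,
                           max_iterations = 2, k = 10,
                           surrogate = if (metric == "random") NULL
                                       else surrogate_spec("rf"),
                           acquisition = acquisition_config(metric), seed = 7)
    r1 <- run_explorer(fx$pool, fx$lookup, cfg)
    r2 <- run_explorer(fx$pool, fx$lookup, cfg)
    expect_identical(r1$explored, r2$explored)
    expect_identical(r1$log, r2$log)
  }
})

test_that("greedy RF beats the random baseline on the synthetic landscape", {
  fx <- cached_fixture(n = 500, noise_sigma = 0.1, k = 25)
  truth <- ground_truth(fx$lookup, 25)
  frac <- function(metric, seed) {
    cfg <- explorer_config(init_size = 0.02, batch_size = 0.02,
                           max_iterations = 5, k = 25,
                           surrogate = if (metric == "random") NULL
                                       else surrogate_spec("rf"),
                           acquisition = acquisition_config(metric),
                           seed = seed)
    top_k_scores_fraction(run_explorer(fx$pool, fx$lookup, cfg), truth)
  }
  seeds <- 1:5
  g <- vapply(seeds, function(s) frac("greedy", s), numeric(1))
  r <- vapply(seeds, function(s) frac("random", s), numeric(1))
  expect_gt(mean(g), mean(r))
})

test_that("missing evaluations consume budget but never enter training or metrics", {
  fx <- cached_fixture(n = 150, noise_sigma = 0.3, missing_frac = 0.3)
  cfg <- explorer_config(init_size = 0.1, batch_size = 0.1,
                         max_iterations = 3, k = 10,
                         surrogate = surrogate_spec("rf"),
                         acquisition = acquisition_config("greedy"), seed = 5)
  rep <- run_explorer(fx$pool, fx$lookup, cfg)
  expect_equal(nrow(rep$explored), 15L + 3L * 15L)
  expect_true(any(is.na(rep$explored$objective_value)))
  expect_true(all(!is.na(rep$top_k$objective_value)))
  # logged scored counts match non-missing acquisitions
  expect_equal(rep$log$n_scored[nrow(rep$log)],
               sum(!is.na(rep$explored$objective_value)))
})

test_that("convergence criterion follows the fractional-difference rule", {
  # flat history: fractional difference 0 -> converged
  expect_true(check_convergence(c(10, 10, 10), current = 10,
                                threshold = 0.01, window = 3))
  # 10% jump is not converged at the 1% threshold
  expect_false(check_convergence(c(10, 10, 10), current = 11,
                                 threshold = 0.01, window = 3))
  # hand-computed: |8.32 - 8.1667| / 8.1667 = 0.0188 >= 0.01
  expect_false(check_convergence(c(8.0, 8.2, 8.3), current = 8.32,
                                 threshold = 0.01, window = 3))
  # fewer than `window` prior iterations: never converged
  expect_false(check_convergence(c(10, 10), current = 10,
                                 threshold = 0.01, window = 3))
  # history-only form: last entry is the current iteration
  expect_true(check_convergence(c(9, 10, 10, 10, 10)))
  # zero rolling mean falls back to the absolute difference
  expect_true(check_convergence(c(0, 0, 0), current = 0.005,
                                threshold = 0.01, window = 3))
  expect_false(check_convergence(c(0, 0, 0), current = 0.5,
                                 threshold = 0.01, window = 3))
  # signed variant: a drop counts as converged (no improvement)
  expect_true(check_convergence(c(10, 10, 10), current = 9.5,
                                threshold = 0.01, window = 3, signed = TRUE))
})

test_that("converged stopping halts a run before the iteration cap", {
  fx <- cached_fixture(n = 200, noise_sigma = 0.3)
  cfg <- explorer_config(init_size = 0.25, batch_size = 0.05,
                         max_iterations = 20, k = 5,
                         stopping = "converged",
                         surrogate = surrogate_spec("rf"),
                         acquisition = acquisition_config("greedy"), seed = 6)
  rep <- run_explorer(fx$pool, fx$lookup, cfg)
  # with a large initialization the top-5 average stabilizes quickly
  expect_true(rep$converged)
  expect_lt(max(rep$explored$iteration_acquired), 20L)
})

test_that("run report writes explored.csv, log.csv and config.yaml", {
  fx <- cached_fixture(n = 100, noise_sigma = 0.3)
  cfg <- explorer_config(init_size = 0.1, batch_size = 0.1, max_iterations = 1,
                         k = 10, surrogate = surrogate_spec("rf"),
                         acquisition = acquisition_config("greedy"), seed = 1)
  rep <- run_explorer(fx$pool, fx$lookup, cfg)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("explored.csv", "log.csv",
                                               "top_k.csv", "config.yaml")))))
  back <- read.csv(file.path(dir, "explored.csv"))
  expect_equal(nrow(back), nrow(rep$explored))
})
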