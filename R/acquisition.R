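# Acquirer: convert surrogate predictions into per-candidate utilities and
# select the top-b untested candidates.

ACQ_METRICS <- c("random", "greedy", "ucb", "ts", "ei", "pi")

#' Acquisition configuration
#'
#' @param metric one of `"random"`, `"greedy"`, `"ucb"`, `"ts"`, `"ei"`,
#'   `"pi"`. All but `random` and `greedy` require the surrogate to provide
#'   a predictive variance.
#' @param beta exploration weight of UCB (utility = mean + beta * sd);
#'   nonnegative, default 2.
#' @param xi improvement margin of EI/PI. The improvement threshold is
#'   `incumbent + xi`, so positive `xi` penalizes exploitation and encourages
#'   exploration; signed values are accepted. Default 0.01.
#' @param seed integer seed for the stochastic metrics (Thompson draws,
#'   random baseline) and for tie-breaking at the batch boundary.
#' @return an `acquisition_config` list.
#' @export
acquisition_config <- function(metric = "greedy", beta = 2, xi = 0.01,
                               seed = 0L) {
  metric <- match.arg(metric, ACQ_METRICS)
  stopifnot(beta >= 0)
  structure(list(metric = metric, beta = beta, xi = xi,
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Per-candidate acquisition utilities
#'
#' Maps predictions to utilities under the configured metric (sd denotes
#' `sqrt(variance)`, `f*` the incumbent — the best *observed* objective
#' value — and `gamma = mean - (f* + xi)`, `z = gamma/sd`):
#' \describe{
#'   \item{greedy}{`mean`}
#'   \item{ucb}{`mean + beta * sd`}
#'   \item{ts}{one draw from `Normal(mean, variance)` per candidate,
#'     independent across candidates}
#'   \item{ei}{`gamma * pnorm(z) + sd * dnorm(z)`; at `sd = 0` the limit
#'     `max(gamma, 0)`}
#'   \item{pi}{`pnorm(z)`; at `sd = 0` the limit `1` if `gamma > 0` else `0`}
#'   \item{random}{one `Uniform(0, 1)` draw per candidate, ignoring the
#'     predictions}
#' }
#' Stochastic metrics consume the caller's RNG stream; seed it for
#' reproducibility.
#'
#' @param config an [acquisition_config()].
#' @param mean numeric vector of predicted means.
#' @param variance numeric vector of predictive variances, or `NULL` for
#'   metrics that do not use it.
#' @param incumbent best observed objective value `f*`; required for EI/PI.
#' @return numeric utility per candidate.
#' @export
acquisition_utility <- function(config, mean, variance = NULL,
                                incumbent = NULL) {
  stopifnot(inherits(config, "acquisition_config"))
  metric <- config$metric
  n <- length(mean)
  if (metric == "random") return(stats::runif(n))
  if (metric %in% c("ucb", "ts", "ei", "pi")) {
    if (is.null(variance))
      stop("metric '", metric, "' requires a predictive variance, ",
           "but the surrogate provides none")
    if (any(variance < 0 | !is.finite(variance)))
      stop("variances must be finite and nonnegative")
    sd <- sqrt(variance)
  }
  switch(metric,
    greedy = mean,
    ucb = mean + config$beta * sd,
    ts = stats::rnorm(n, mean = mean, sd = sd),
    ei = {
      if (is.null(incumbent)) stop("EI requires the incumbent f*")
      gamma <- mean - (incumbent + config$xi)
      u <- pmax(gamma, 0)   # sd = 0 limit
      pos <- sd > 0
      z <- gamma[pos] / sd[pos]
      u[pos] <- gamma[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
      u
    },
    pi = {
      if (is.null(incumbent)) stop("PI requires the incumbent f*")
      gamma <- mean - (incumbent + config$xi)
      u <- as.numeric(gamma > 0)  # sd = 0 limit
      pos <- sd > 0
      u[pos] <- stats::pnorm(gamma[pos] / sd[pos])
      u
    })
}

#' Select the top-b untested candidates by utility
#'
#' Returns the `b` untested candidates with the largest utilities. Ties at
#' the batch boundary are broken uniformly at random from the caller's RNG
#' stream; candidates strictly above the cut are always included.
#'
#' @param utilities numeric utility per pool candidate.
#' @param tested logical vector (or integer index set) of already-acquired
#'   candidates, excluded from selection.
#' @param b batch size; if it exceeds the number of untested candidates it is
#'   truncated with a warning (final-iteration edge case).
#' @return integer vector of exactly `min(b, n_untested)` candidate indices.
#' @export
select_batch <- function(utilities, tested = NULL, b = 1L) {
  n <- length(utilities)
  mask <- rep(FALSE, n)
  if (!is.null(tested)) {
    if (is.logical(tested)) mask <- tested else mask[tested] <- TRUE
  }
  untested <- which(!mask)
  if (length(untested) == 0L) stop("no untested candidates remain")
  if (b > length(untested)) {
    warning("batch size ", b, " exceeds ", length(untested),
            " untested candidates; truncating")
    b <- length(untested)
  }
  u <- utilities[untested]
  if (any(!is.finite(u))) stop("utilities must be finite")
  cut <- sort(u, decreasing = TRUE)[b]
  sure <- untested[u > cut]
  ties <- untested[u == cut]
  need <- b - length(sure)
  picked <- if (length(ties) > need) sample(ties, need) else ties
  sort(c(sure, picked))
}
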