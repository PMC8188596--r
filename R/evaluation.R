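# Retrieval metrics for a completed run against a ground-truth score table:
# average top-k ratio, top-k SMILES fraction, top-k scores fraction
# (multiset, tie-robust), enrichment factor, and repeat-overlap analysis.

#' Build the ground truth from a full score table
#'
#' Ranks every scored molecule of the library by objective value. Ties at
#' rank k are resolved deterministically by a stable sort on
#' (objective descending, canonical SMILES ascending); the Scores metric is
#' the tie-robust one by construction.
#'
#' @param table a `lookup_table` covering the whole library.
#' @param k top-k size.
#' @return a `ground_truth`: list with `smiles`/`objective` (all scored
#'   molecules, sorted), `top_smiles`, `top_objective` (length k), `k`,
#'   `minimize`.
#' @export
ground_truth <- function(table, k) {
  stopifnot(inherits(table, "lookup_table"), k >= 1)
  scored <- table$scores[!is.na(table$scores)]
  if (length(scored) < k)
    stop("ground truth has ", length(scored), " scored molecules; k = ", k)
  obj <- if (table$minimize) -scored else scored
  ord <- order(-obj, names(obj))
  structure(list(smiles = names(obj)[ord], objective = unname(obj[ord]),
                 top_smiles = names(obj)[ord][seq_len(k)],
                 top_objective = unname(obj[ord])[seq_len(k)],
                 k = as.integer(k), minimize = table$minimize),
            class = "ground_truth")
}

# best-k found molecules under the same deterministic tie rule
found_top_k <- function(found, k) {
  found <- found[!is.na(found$objective_value), , drop = FALSE]
  ord <- order(-found$objective_value, found$smiles)
  found[ord[seq_len(min(k, nrow(found)))], , drop = FALSE]
}

as_found <- function(found) {
  if (inherits(found, "explorer_report")) return(found$explored)
  stopifnot(is.data.frame(found),
            all(c("smiles", "objective_value") %in% names(found)))
  found
}

#' Average top-k score ratio
#'
#' Mean of the k best found objective values divided by the mean of the true
#' top-k. Signs are preserved: the ratio is identical whether computed on
#' raw or negated scores, and equals 1 exactly when the found top-k score
#' multiset matches the truth's.
#'
#' @param found an `explorer_report` or a data.frame with `smiles` and
#'   `objective_value` columns (missing evaluations `NA`).
#' @param truth a [ground_truth()].
#' @param k top-k size (default: the truth's k).
#' @return the ratio; if fewer than k molecules were found the ratio is
#'   computed over all found and flagged with attribute `partial = TRUE`.
#' @export
top_k_average_ratio <- function(found, truth, k = truth$k) {
  found <- as_found(found)
  top <- found_top_k(found, k)
  out <- mean(top$objective_value) / mean(truth$top_objective[seq_len(k)])
  if (nrow(top) < k) attr(out, "partial") <- TRUE
  out
}

#' Fraction of true top-k molecules identified
#'
#' Size of the intersection between the found top-k and true top-k SMILES
#' sets, divided by k.
#'
#' @inheritParams top_k_average_ratio
#' @return fraction in `[0, 1]`.
#' @export
top_k_smiles_fraction <- function(found, truth, k = truth$k) {
  found <- as_found(found)
  top <- found_top_k(found, k)
  out <- length(intersect(top$smiles, truth$top_smiles[seq_len(k)])) / k
  if (nrow(top) < k) attr(out, "partial") <- TRUE
  out
}

#' Fraction of true top-k score values identified
#'
#' Multiset intersection of the k best found score values with the true
#' top-k score values, divided by k. Comparison is exact on the values as
#' parsed (score tables carry fixed printed precision), which makes this the
#' tie-robust metric: molecules with equal scores are interchangeable.
#'
#' @inheritParams top_k_average_ratio
#' @return fraction in `[0, 1]`; never smaller than the SMILES fraction on
#'   the same run.
#' @export
top_k_scores_fraction <- function(found, truth, k = truth$k) {
  found <- as_found(found)
  top <- found_top_k(found, k)
  a <- table(top$objective_value)
  b <- table(truth$top_objective[seq_len(k)])
  common <- intersect(names(a), names(b))
  out <- sum(pmin(a[common], b[common])) / k
  if (nrow(top) < k) attr(out, "partial") <- TRUE
  unname(out)
}

#' Enrichment factor over random search
#'
#' Ratio of the top-k recovery of a model-guided search to that of a random
#' search at the same number of objective function evaluations.
#'
#' @param model_fraction recovery of the guided search (e.g. scores
#'   fraction, or a percentage — units cancel).
#' @param random_fraction recovery of the random baseline, same units.
#' @return the enrichment factor; `NA` (undefined) when the random baseline
#'   found nothing.
#' @examples
#' enrichment_factor(51.6, 5.6) # 9.2
#' enrichment_factor(66.8, 5.6) # 11.9
#' @export
enrichment_factor <- function(model_fraction, random_fraction) {
  stopifnot(model_fraction >= 0, random_fraction >= 0)
  if (random_fraction == 0) return(NA_real_)
  model_fraction / random_fraction
}

#' Acquisition overlap across repeated runs
#'
#' For repeated runs with identical batch schedules, counts the cumulative
#' number of unique molecules acquired across all runs at each iteration,
#' together with the theoretical bounds: the maximum is all runs acquiring
#' disjoint sets (capped by the pool size), the minimum is identical
#' acquisition after the (possibly different) random initializations.
#'
#' @param runs list of runs; each run is a list of per-iteration character
#'   vectors of acquired SMILES (entry 1 = initialization).
#' @param pool_size optional pool size capping the maximum bound.
#' @return data.frame with columns `iteration` (0-based), `n_unique`,
#'   `min_bound`, `max_bound`.
#' @export
repeat_overlap <- function(runs, pool_size = Inf) {
  stopifnot(length(runs) >= 2)
  n_iter <- unique(vapply(runs, length, integer(1)))
  if (length(n_iter) != 1)
    stop("runs have different numbers of iterations")
  sizes <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    si <- unique(vapply(runs, function(r) length(r[[i]]), integer(1)))
    if (length(si) != 1)
      stop("runs have different batch sizes at iteration ", i - 1)
    sizes[i] <- si
  }
  init_union <- length(unique(unlist(lapply(runs, `[[`, 1))))
  out <- data.frame(iteration = seq_len(n_iter) - 1L, n_unique = NA_integer_,
                    min_bound = NA_integer_, max_bound = NA_integer_)
  seen <- character(0)
  cum_batch <- 0L
  for (i in seq_len(n_iter)) {
    cum_batch <- cum_batch + sizes[i]
    seen <- unique(c(seen, unlist(lapply(runs, `[[`, i))))
    out$n_unique[i] <- length(seen)
    out$max_bound[i] <- min(length(runs) * cum_batch, pool_size)
    out$min_bound[i] <- if (i == 1) init_union else init_union + cum_batch - sizes[1]
  }
  out
}
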