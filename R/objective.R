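# LookupObjective: replay of a precomputed score table (e.g. docking scores).
# The package-wide convention is maximization; negation of minimized raw
# scores (docking: more negative is better) happens exactly once, here.

#' Load a SMILES -> score lookup table
#'
#' Builds the objective for retrospective screening from a CSV (optionally
#' gzipped) of molecules and precomputed scores. Keys are canonicalized with
#' the same rule as pool loading so molecules match across tools. Rows with
#' an empty, non-numeric, or sentinel score are kept as *key present, score
#' missing* — mirroring ligands that failed to dock: they can be acquired
#' (consuming budget) but return no objective value.
#'
#' @param path CSV file path.
#' @param smiles_column,score_column column names or 1-based positions.
#' @param minimize if `TRUE` (the docking default), lower raw scores are
#'   better and the objective is the negated raw score.
#' @param sentinel_values raw score values to treat as missing (e.g. the
#'   placeholder 10000 used by some docking pipelines).
#' @return a `lookup_table`: list with `scores` (named numeric, canonical
#'   SMILES -> raw score, `NA` = missing), `minimize`, and `load_report`
#'   (`n_scored`, `n_missing`, `n_sentinel_dropped`).
#' @export
load_lookup <- function(path, smiles_column = "smiles", score_column = "score",
                        minimize = TRUE, sentinel_values = numeric(0)) {
  stopifnot(file.exists(path))
  dt <- fread_maybe_gz(path)
  pick <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(dt)) stop(what, " column '", col, "' not found in ", path)
      dt[[col]]
    } else {
      if (col > ncol(dt)) stop(what, " column position ", col, " out of range")
      dt[[names(dt)[col]]]
    }
  }
  smi <- as.character(pick(smiles_column, "SMILES"))
  raw <- suppressWarnings(as.numeric(pick(score_column, "score")))
  lookup_from_table(smi, raw, minimize = minimize,
                    sentinel_values = sentinel_values)
}

#' Build a lookup table from in-memory vectors
#'
#' @param smiles character vector of SMILES keys.
#' @param scores numeric raw scores (`NA` = missing).
#' @inheritParams load_lookup
#' @return a `lookup_table`.
#' @export
lookup_from_table <- function(smiles, scores, minimize = TRUE,
                              sentinel_values = numeric(0)) {
  stopifnot(length(smiles) == length(scores))
  canon <- canonicalize_smiles(smiles)
  keep <- !is.na(canon)
  canon <- canon[keep]
  scores <- scores[keep]
  n_sentinel <- 0L
  if (length(sentinel_values)) {
    is_sent <- scores %in% sentinel_values
    n_sentinel <- sum(is_sent, na.rm = TRUE)
    scores[is_sent] <- NA_real_
  }
  scores[!is.finite(scores)] <- NA_real_
  dup <- duplicated(canon)
  canon <- canon[!dup]
  scores <- scores[!dup]
  if (length(canon) == 0L) stop("lookup table has no parseable rows")
  names(scores) <- canon
  structure(list(
    scores = scores,
    minimize = isTRUE(minimize),
    load_report = list(n_scored = sum(!is.na(scores)),
                       n_missing = sum(is.na(scores)),
                       n_sentinel_dropped = n_sentinel)
  ), class = "lookup_table")
}

#' @export
print.lookup_table <- function(x, ...) {
  r <- x$load_report
  cat(sprintf("lookup_table: %d molecules (%d scored, %d missing), %s\n",
              length(x$scores), r$n_scored, r$n_missing,
              if (x$minimize) "minimized raw scores (objective = -score)"
              else "maximized raw scores"))
  invisible(x)
}

#' Evaluate a batch of molecules against the lookup objective
#'
#' Returns one result per input SMILES, order preserved. Molecules absent
#' from the table or present without a score evaluate to `NA` (missing);
#' missing evaluations still consume acquisition budget upstream but are
#' excluded from surrogate training and from metric numerators.
#'
#' @param table a `lookup_table`.
#' @param batch character vector of canonical SMILES.
#' @return data.frame with columns `smiles`, `raw_score` and
#'   `objective_value` (maximization convention: `-raw_score` when the table
#'   is minimized).
#' @export
evaluate_batch <- function(table, batch) {
  stopifnot(inherits(table, "lookup_table"), length(batch) >= 1)
  raw <- unname(table$scores[batch])   # NA where key absent or score missing
  obj <- if (table$minimize) -raw else raw
  data.frame(smiles = batch, raw_score = raw, objective_value = obj,
             stringsAsFactors = FALSE)
}

#' Report pool coverage of a lookup table
#'
#' Pre-run diagnostic: how many pool members have a score, are present
#' without a score, or are absent from the table entirely.
#'
#' @param pool a `molecule_pool`.
#' @param table a `lookup_table`.
#' @return list with `n_scored`, `n_missing_score`, `n_absent`.
#' @export
lookup_coverage <- function(pool, table) {
  present <- pool$smiles %in% names(table$scores)
  scored <- present & !is.na(table$scores[pool$smiles])
  list(n_scored = sum(scored),
       n_missing_score = sum(present & !scored),
       n_absent = sum(!present))
}
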