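# Synthetic pools and score tables with a controlled structure-score
# landscape, so the full optimization loop is testable without any external
# dataset. Molecules are heteroatom-substituted branched alkyl chains
# enumerated from a small grammar; scores are a smooth deterministic
# function of the same 2048-bit fingerprint the surrogates see, plus
# Gaussian noise — a deliberately learnable landscape.

#' Specify a synthetic structure-score landscape
#'
#' @param n_molecules number of unique molecules to generate (>= 10).
#' @param generator `"combinatorial-chains"`: branched C/N/O/S chains (no
#'   adjacent heteroatoms) sampled from a seeded grammar.
#' @param weight_seed seed for the landscape weight vector, separate from
#'   the structural seed so the same chemistry can carry different
#'   landscapes.
#' @param noise_sigma standard deviation of the additive Gaussian noise on
#'   the raw score, in score units; with `noise_relative = TRUE`, a fraction
#'   of the realized standard deviation of the noiseless signal instead.
#' @param score_function `"linear-in-bits"` (raw score
#'   `-(w . fp)` + noise) or `"quadratic-in-bits"` (adds a squared second
#'   projection for curvature).
#' @param tie_quantization optional decimal precision for rounding raw
#'   scores (e.g. 0.1 emulates the coarse grid of Vina scores, making ties
#'   common); `NULL` disables.
#' @param missing_frac fraction of molecules whose score is withheld,
#'   emulating ligands that failed to dock.
#' @param noise_relative interpret `noise_sigma` as a fraction of the signal
#'   standard deviation (default `FALSE`).
#' @return a `landscape_spec`.
#' @export
landscape_spec <- function(n_molecules = 1000L,
                           generator = "combinatorial-chains",
                           weight_seed = 1L, noise_sigma = 0,
                           score_function = c("linear-in-bits",
                                              "quadratic-in-bits"),
                           tie_quantization = NULL, missing_frac = 0,
                           noise_relative = FALSE) {
  generator <- match.arg(generator, "combinatorial-chains")
  score_function <- match.arg(score_function)
  stopifnot(n_molecules >= 10, noise_sigma >= 0,
            missing_frac >= 0, missing_frac < 1)
  structure(list(n_molecules = as.integer(n_molecules), generator = generator,
                 weight_seed = as.integer(weight_seed),
                 noise_sigma = noise_sigma, score_function = score_function,
                 tie_quantization = tie_quantization,
                 missing_frac = missing_frac,
                 noise_relative = isTRUE(noise_relative)),
            class = "landscape_spec")
}

# seeded random branched chains over C/N/O/S; heteroatoms never adjacent
random_chain_smiles <- function(n) {
  hetero <- c("N", "O", "S")
  build_one <- function() {
    len <- sample(3:10, 1)
    atoms <- character(len)
    prev_het <- TRUE  # no heteroatom start
    for (i in seq_len(len)) {
      if (!prev_het && stats::runif(1) < 0.3) {
        atoms[i] <- sample(hetero, 1); prev_het <- TRUE
      } else {
        atoms[i] <- "C"; prev_het <- FALSE
      }
    }
    # up to two methyl/ethyl branches on interior carbons
    n_branch <- sample(0:2, 1)
    for (b in seq_len(n_branch)) {
      pos <- which(atoms == "C")
      pos <- pos[pos > 1 & pos < len]
      if (!length(pos)) break
      i <- if (length(pos) == 1) pos else sample(pos, 1)
      atoms[i] <- paste0(atoms[i], if (stats::runif(1) < 0.5) "(C)" else "(CC)")
    }
    paste(atoms, collapse = "")
  }
  vapply(seq_len(n), function(i) build_one(), character(1))
}

#' Generate a synthetic pool, lookup table, and ground-truth record
#'
#' Draws unique valid molecules from the grammar, featurizes them, computes
#' raw scores as a deterministic function of the fingerprint plus noise, and
#' writes three plain-text files: a `.smi` pool file, a lookup CSV
#' (`smiles,score`; withheld scores are empty), and a JSON truth file
#' recording the landscape weights, the generation parameters, and the
#' exact top-k. Byte-identical for a fixed seed.
#'
#' @param spec a [landscape_spec()].
#' @param seed structural seed driving molecule sampling, noise, and
#'   missingness.
#' @param dir output directory (created if needed).
#' @param k top-k recorded in the truth file (default 100, capped at pool
#'   size).
#' @return list with `pool_file`, `lookup_file`, `truth_file`, and the
#'   in-memory `pool` (featurized `molecule_pool`), `lookup`
#'   (`lookup_table`, minimize convention), `raw_scores`, `signal`
#'   (noiseless signal, maximization convention).
#' @export
generate_pool <- function(spec, seed, dir = tempfile("landscape"), k = 100L) {
  stopifnot(inherits(spec, "landscape_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(seed, 1L))
  n <- spec$n_molecules
  canon <- character(0)
  budget <- 60L * n
  tried <- 0L
  while (length(canon) < n && tried < budget) {
    take <- min(max(2L * (n - length(canon)), 500L), budget - tried)
    tried <- tried + take
    cand <- random_chain_smiles(take)
    cc <- canonicalize_smiles(cand)
    cc <- cc[!is.na(cc)]
    canon <- unique(c(canon, cc))
  }
  if (length(canon) < n)
    stop("could not generate ", n, " unique molecules within the collision budget")
  canon <- canon[seq_len(n)]

  pool <- pool_from_smiles(canon)
  fp <- pool$fingerprints

  set.seed(derive_seed(spec$weight_seed, 2L))
  w <- stats::rnorm(FP_NBITS)
  signal <- as.numeric(fp %*% w)
  w2 <- NULL
  if (spec$score_function == "quadratic-in-bits") {
    w2 <- stats::rnorm(FP_NBITS) / sqrt(FP_NBITS)
    signal <- signal + 0.5 * as.numeric(fp %*% w2)^2
  }

  set.seed(derive_seed(seed, 3L))
  sigma <- if (isTRUE(spec$noise_relative)) spec$noise_sigma * stats::sd(signal)
           else spec$noise_sigma
  noise <- if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  raw <- -(signal) + noise
  if (!is.null(spec$tie_quantization))
    raw <- round(raw / spec$tie_quantization) * spec$tie_quantization
  missing <- rep(FALSE, n)
  if (spec$missing_frac > 0)
    missing[sample.int(n, round(spec$missing_frac * n))] <- TRUE

  pool_file <- file.path(dir, "pool.smi")
  writeLines(pool$smiles, pool_file)
  lookup_file <- file.path(dir, "lookup.csv")
  score_col <- formatC(raw, format = "g", digits = 15)
  score_col[missing] <- ""
  writeLines(c("smiles,score", paste(pool$smiles, score_col, sep = ",")),
             lookup_file)

  k_eff <- min(k, sum(!missing))
  ord <- order(raw + ifelse(missing, Inf, 0), pool$smiles)[seq_len(k_eff)]
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(spec = unclass(spec), seed = seed, weights = w,
         weights_quadratic = w2,
         top_k = data.frame(smiles = pool$smiles[ord], raw_score = raw[ord])),
    truth_file, auto_unbox = TRUE, digits = NA, null = "null")

  lookup <- lookup_from_table(pool$smiles, ifelse(missing, NA_real_, raw),
                              minimize = TRUE)
  list(pool_file = pool_file, lookup_file = lookup_file,
       truth_file = truth_file, pool = pool, lookup = lookup,
       raw_scores = ifelse(missing, NA_real_, raw), signal = signal)
}

#' Oracle surrogate: a perfect-model test double
#'
#' A `surrogate_model` whose predicted mean equals the true objective value
#' and whose variance is exactly zero, for perfect-model-limit tests (with
#' greedy acquisition it must select exactly the true top-b untested
#' molecules). Pool members without a score predict just below the worst
#' scored value.
#'
#' @param lookup a `lookup_table` holding the true scores.
#' @return a `surrogate_model` usable with [predict_surrogate()].
#' @export
oracle_surrogate <- function(lookup) {
  stopifnot(inherits(lookup, "lookup_table"))
  structure(list(lookup = lookup,
                 spec = list(architecture = "oracle", uncertainty = "exact")),
            class = c("surrogate_oracle", "surrogate_model"))
}

#' @export
predict_surrogate.surrogate_oracle <- function(model, pool) {
  raw <- unname(model$lookup$scores[pool$smiles])
  obj <- if (model$lookup$minimize) -raw else raw
  floor_val <- if (any(!is.na(obj))) min(obj, na.rm = TRUE) - 1 else 0
  obj[is.na(obj)] <- floor_val
  check_prediction(list(mean = obj, variance = rep(0, pool$size)), pool$size)
}
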