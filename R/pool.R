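# MoleculePool: the finite design space of candidate molecules, loaded from
# SMILES/CSV files, canonicalized, deduplicated, and featurized once.

#' Load a molecule pool from SMILES or CSV files
#'
#' Reads one or more files (`.smi` with one SMILES per line and an optional
#' whitespace-separated ID column, or delimited files with a SMILES column;
#' gzip transparently supported), canonicalizes every SMILES, drops
#' unparseable rows and duplicate molecules (first occurrence kept, file
#' order preserved), and computes the 2048-bit atom-pair fingerprint of each
#' unique molecule exactly once.
#'
#' @param paths character vector of file paths.
#' @param smiles_column column name or 1-based position holding the SMILES
#'   in delimited files; ignored for `.smi` files (first token is taken).
#' @param fingerprints compute fingerprints at load (default `TRUE`).
#'   Molecular graphs are retained for graph-based surrogates.
#' @param cache_file optional path to an on-disk fingerprint cache, keyed by
#'   the MD5 checksums of the input files; reused when the inputs match.
#' @return an object of class `molecule_pool`: a list with `smiles`
#'   (canonical, unique), `input_smiles` (as read), `fingerprints`
#'   (size x 2048 integer matrix), `graphs`, `size`, and `load_report`
#'   (`n_read`, `n_invalid`, `n_duplicate`).
#' @export
load_pool <- function(paths, smiles_column = 1L, fingerprints = TRUE,
                      cache_file = NULL) {
  stopifnot(length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("pool file(s) not found: ", paste(missing, collapse = ", "))
  raw <- unlist(lapply(paths, read_smiles_file, smiles_column = smiles_column),
                use.names = FALSE)
  pool_from_smiles(raw, fingerprints = fingerprints,
                   cache_key = if (!is.null(cache_file))
                     list(file = cache_file, md5 = unname(tools::md5sum(paths)))
                   else NULL)
}

read_smiles_file <- function(path, smiles_column = 1L) {
  is_smi <- grepl("\\.smi(\\.gz)?$", path, ignore.case = TRUE) ||
    grepl("\\.txt(\\.gz)?$", path, ignore.case = TRUE)
  if (is_smi) {
    lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path,
                       warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    return(vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1))
  }
  dt <- fread_maybe_gz(path, colClasses = "character")
  if (is.character(smiles_column)) {
    if (!smiles_column %in% names(dt))
      stop("SMILES column '", smiles_column, "' not found in ", path)
    col <- smiles_column
  } else {
    if (smiles_column > ncol(dt))
      stop("SMILES column position ", smiles_column, " exceeds ", ncol(dt),
           " columns in ", path)
    col <- names(dt)[smiles_column]
  }
  dt[[col]]
}

#' Build a pool from in-memory SMILES
#'
#' Same canonicalization, deduplication and featurization as [load_pool()]
#' but starting from a character vector.
#'
#' @param smiles character vector.
#' @inheritParams load_pool
#' @param cache_key internal cache descriptor.
#' @return a `molecule_pool`.
#' @export
pool_from_smiles <- function(smiles, fingerprints = TRUE, cache_key = NULL) {
  n_read <- length(smiles)
  canon <- canonicalize_smiles(smiles)
  valid <- !is.na(canon)
  n_invalid <- sum(!valid)
  smiles <- smiles[valid]
  canon <- canon[valid]
  dup <- duplicated(canon)
  n_duplicate <- sum(dup)
  smiles <- smiles[!dup]
  canon <- canon[!dup]
  if (length(canon) == 0L)
    stop("empty pool: no valid unique molecules after filtering")
  pool <- structure(list(
    smiles = canon,
    input_smiles = smiles,
    fingerprints = NULL,
    graphs = NULL,
    size = length(canon),
    load_report = list(n_read = n_read, n_invalid = n_invalid,
                       n_duplicate = n_duplicate)
  ), class = "molecule_pool")
  if (fingerprints) {
    cached <- read_fp_cache(cache_key, canon)
    if (!is.null(cached)) {
      pool$fingerprints <- cached$fingerprints
      pool$graphs <- cached$graphs
    } else {
      pool$graphs <- parse_molecules(canon)
      fp <- matrix(0L, nrow = length(canon), ncol = FP_NBITS)
      for (i in seq_along(canon)) {
        if (is.null(pool$graphs[[i]])) stop("canonical SMILES failed to re-parse: ", canon[i])
        fp[i, ] <- fingerprint_graph(pool$graphs[[i]])
      }
      pool$fingerprints <- fp
      write_fp_cache(cache_key, canon, fp, pool$graphs)
    }
  }
  pool
}

read_fp_cache <- function(cache_key, canon) {
  if (is.null(cache_key) || !file.exists(cache_key$file)) return(NULL)
  cache <- tryCatch(readRDS(cache_key$file), error = function(e) NULL)
  if (is.null(cache)) return(NULL)
  if (!identical(cache$md5, cache_key$md5)) return(NULL)
  if (!identical(cache$smiles, canon)) return(NULL)
  cache
}

write_fp_cache <- function(cache_key, canon, fp, graphs) {
  if (is.null(cache_key)) return(invisible(NULL))
  saveRDS(list(md5 = cache_key$md5, smiles = canon, fingerprints = fp,
               graphs = graphs), cache_key$file)
  invisible(NULL)
}

#' @export
print.molecule_pool <- function(x, ...) {
  cat("molecule_pool of", x$size, "unique molecules\n")
  r <- x$load_report
  cat(sprintf("  read %d rows: %d invalid, %d duplicate dropped\n",
              r$n_read, r$n_invalid, r$n_duplicate))
  cat("  fingerprints:", if (is.null(x$fingerprints)) "not computed"
      else paste0(ncol(x$fingerprints), "-bit, precomputed"), "\n")
  invisible(x)
}

#' Subsample a pool uniformly without replacement
#'
#' @param pool a `molecule_pool`.
#' @param n number of molecules to keep, `0 < n <= pool$size`.
#' @param seed integer seed; the same seed always selects the same subset.
#' @return a `molecule_pool` of size `n` (membership deterministic per seed;
#'   candidates keep their relative file order).
#' @export
subsample_pool <- function(pool, n, seed) {
  stopifnot(inherits(pool, "molecule_pool"))
  if (n <= 0 || n > pool$size)
    stop("n must be in [1, pool size]; got ", n, " for pool of ", pool$size)
  idx <- withr_seed(seed, sample.int(pool$size, n))
  idx <- sort(idx)
  out <- pool
  out$smiles <- pool$smiles[idx]
  out$input_smiles <- pool$input_smiles[idx]
  out$fingerprints <- pool$fingerprints[idx, , drop = FALSE]
  out$graphs <- pool$graphs[idx]
  out$size <- length(idx)
  out$load_report$subsampled_from <- pool$size
  out
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
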