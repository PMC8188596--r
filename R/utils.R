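#' Convert a fraction or count to a whole number of molecules
#'
#' Fractional sizes (values strictly below 1) are interpreted relative to
#' `total` and converted by taking the ceiling, with a floor of one molecule
#' (so 1% of a 10,560-member library is 106 molecules and 1% of 50,240 is
#' 503); values of 1 or more are taken as absolute counts.
#'
#' @param x fraction in (0, 1) or absolute count >= 1.
#' @param total pool size the fraction refers to.
#' @return integer count, at least 1.
#' @examples
#' frac_to_count(0.01, 10560) # 106
#' frac_to_count(0.01, 50240) # 503
#' @export
frac_to_count <- function(x, total) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0, total >= 1)
  if (x >= 1) return(as.integer(round(x)))
  max(1L, as.integer(ceiling(x * total - 1e-9)))
}

# Derive a 32-bit-safe stream seed from a run seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + stream * 9176) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fread with transparent gzip support (no optional-dependency decompression)
fread_maybe_gz <- function(path, ...) {
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    data.table::fread(text = lines, header = "auto", showProgress = FALSE, ...)
  } else {
    data.table::fread(path, header = "auto", showProgress = FALSE, ...)
  }
}
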