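# SMILES handling: syntactic validation, canonicalization, and parsing to
# molecular graphs. OpenBabel (via ChemmineOB) does the chemistry; a
# syntactic prefilter rejects malformed strings that OpenBabel would
# silently "repair" (e.g. unbalanced parentheses).

SMILES_CHARS <- "^[A-Za-z0-9@+\\-\\[\\]\\(\\)=#$:/\\\\.%*]+$"

#' Check SMILES strings for basic syntactic validity
#'
#' Verifies the character set, balanced parentheses and brackets, and paired
#' ring-closure digits. This is a prefilter, not a full grammar: strings that
#' pass may still fail chemical perception downstream.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @keywords internal
smiles_syntax_ok <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s) || !grepl(SMILES_CHARS, s, perl = TRUE)) return(FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
    if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (any(depth < 0)) return(FALSE)
    # ring-closure digits outside brackets must pair up
    in_br <- cumsum((chars == "[")) - cumsum((chars == "]"))
    ring <- chars[in_br == 0 & grepl("[0-9]", chars)]
    all(table(ring) %% 2 == 0)
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Returns the OpenBabel canonical SMILES for each input, or `NA` for strings
#' that fail the syntactic prefilter or chemical perception. Duplicate
#' detection and lookup-table matching throughout the package operate on
#' these canonical strings, so pools and score tables generated by different
#' tools can be matched by molecule identity.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of the same length; `NA` where invalid.
#' @examples
#' \donttest{
#' canonicalize_smiles(c("OCC", "CCO", "C(C"))  # first two agree, third is NA
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- smiles_syntax_ok(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  input <- paste(smiles[idx], paste0("id", idx), collapse = "\n")
  res <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(input, "\n"))
  )
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2 && grepl("^id[0-9]+$", p[2])) {
      i <- as.integer(sub("^id", "", p[2]))
      out[i] <- p[1]
    }
  }
  out
}

#' Parse SMILES into molecular graphs
#'
#' Converts SMILES to kekulized connection tables via OpenBabel and extracts,
#' per molecule, the heavy-atom element symbols and the bond list with bond
#' orders. Hydrogens are implicit (hydrogen-suppressed graphs).
#'
#' @param smiles character vector of valid SMILES.
#' @return a list with one entry per molecule: `list(elements = character,
#'   bonds = matrix with columns a1, a2, order)`, or `NULL` where parsing
#'   failed.
#' @keywords internal
parse_molecules <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  if (n == 0L) return(out)
  ok <- smiles_syntax_ok(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  input <- paste(smiles[idx], paste0("id", idx), collapse = "\n")
  sdf_txt <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(input, "\n"))
  )
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  ids <- ChemmineR::sdfid(sdfset)
  for (j in seq_along(sdfset)) {
    if (!grepl("^id[0-9]+$", ids[j])) next
    i <- as.integer(sub("^id", "", ids[j]))
    sdf <- sdfset[[j]]
    # ChemmineR mis-parses 0/1-atom records; trust the V2000 counts line
    counts <- ChemmineR::header(sdf)[["Counts_Line"]]
    natoms <- as.integer(substr(counts, 1, 3))
    nbonds <- as.integer(substr(counts, 4, 6))
    if (is.na(natoms) || natoms < 1L) next
    if (natoms == 1L) {
      # ChemmineR's atomblock is unreliable for 1-atom records; the single
      # heavy atom's element is recoverable from the SMILES itself
      m <- regmatches(smiles[i], regexpr("[A-Z][a-z]?", smiles[i]))
      out[[i]] <- list(elements = if (length(m)) m else "C",
                       bonds = matrix(integer(0), ncol = 3,
                                      dimnames = list(NULL, c("a1", "a2", "order"))))
      next
    }
    ab <- ChemmineR::atomblock(sdf)
    elements <- sub("_[0-9]+$", "", rownames(ab))
    if (nbonds >= 1L) {
      bb <- ChemmineR::bondblock(sdf)
      bonds <- cbind(a1 = as.integer(bb[, 1]),
                     a2 = as.integer(bb[, 2]),
                     order = as.integer(bb[, 3]))
    } else {
      bonds <- matrix(integer(0), ncol = 3,
                      dimnames = list(NULL, c("a1", "a2", "order")))
    }
    out[[i]] <- list(elements = elements, bonds = bonds)
  }
  out
}
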