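# 2048-bit hashed atom-pair fingerprints.
#
# Carhart-style atom pairs: every unordered pair of heavy atoms at
# topological (bond-path) distance 1 to 3 contributes one feature
# (type_i, type_j, distance), which is hashed onto a fixed-width bit
# vector. Atom type encodes element, heavy-atom degree, and pi-electron
# count. Presence/absence only (binary, not counts).

FP_NBITS <- 2048L
FP_MIN_DIST <- 1L
FP_MAX_DIST <- 3L

# fixed element table; anything else maps to the final "other" code
FP_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "Si", "B")

# Atom type code: element index, heavy degree (capped 7), pi electrons (capped 7).
atom_type_codes <- function(elements, bonds) {
  n <- length(elements)
  degree <- integer(n)
  pi_e <- integer(n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]; b <- bonds[r, 2]; o <- bonds[r, 3]
      degree[a] <- degree[a] + 1L; degree[b] <- degree[b] + 1L
      extra <- max(0L, min(o, 3L) - 1L)  # pi electrons from double/triple bonds
      pi_e[a] <- pi_e[a] + extra; pi_e[b] <- pi_e[b] + extra
    }
  }
  el <- match(elements, FP_ELEMENTS)
  el[is.na(el)] <- length(FP_ELEMENTS) + 1L
  el * 64L + pmin(degree, 7L) * 8L + pmin(pi_e, 7L)
}

# Deterministic hash of an atom-pair feature onto [0, nbits).
# Types are sorted so the pair is unordered.
hash_pair <- function(t1, t2, dist, nbits = FP_NBITS) {
  lo <- pmin(t1, t2); hi <- pmax(t1, t2)
  ((lo * 7919 + hi) * 31 + dist * 2029) %% nbits
}

# Topological distance classes 1..3 from the adjacency matrix: the shortest
# path length is the smallest k for which a length-k walk exists.
pair_distances_123 <- function(n, bonds) {
  A <- matrix(0L, n, n)
  if (nrow(bonds) > 0) {
    A[cbind(bonds[, 1], bonds[, 2])] <- 1L
    A[cbind(bonds[, 2], bonds[, 1])] <- 1L
  }
  W2 <- A %*% A
  W3 <- W2 %*% A
  eye <- diag(n) > 0
  d1 <- A > 0
  d2 <- W2 > 0 & !d1 & !eye
  d3 <- W3 > 0 & !d2 & !d1 & !eye
  list(d1 = d1, d2 = d2, d3 = d3)
}

# Fingerprint from a parsed molecular graph.
fingerprint_graph <- function(graph, nbits = FP_NBITS) {
  fp <- integer(nbits)
  n <- length(graph$elements)
  if (n < 2L) return(fp)
  types <- atom_type_codes(graph$elements, graph$bonds)
  dists <- pair_distances_123(n, graph$bonds)
  for (d in FP_MIN_DIST:FP_MAX_DIST) {
    mask <- dists[[d]]
    pairs <- which(mask & upper.tri(mask), arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    bits <- hash_pair(types[pairs[, 1]], types[pairs[, 2]], d, nbits)
    fp[bits + 1L] <- 1L
  }
  fp
}

#' Compute a 2048-bit atom-pair fingerprint
#'
#' Enumerates all unordered pairs of heavy atoms at topological distances
#' 1 to 3 bonds, types each atom by (element, heavy-atom degree, pi-electron
#' count), and hashes each (type, type, distance) feature onto a 2048-bit
#' binary vector. Hydrogens are implicit. Molecules with a single heavy atom
#' have no atom pairs and yield the all-zero vector.
#'
#' @param smiles character vector of valid SMILES.
#' @return integer matrix with one row per molecule and 2048 columns of 0/1.
#'   Rows for unparseable SMILES are `NA`.
#' @examples
#' \donttest{
#' fp <- featurize(c("CCO", "c1ccccc1"))
#' dim(fp)       # 2 x 2048
#' range(fp)     # 0 1
#' }
#' @export
featurize <- function(smiles) {
  graphs <- parse_molecules(smiles)
  out <- matrix(NA_integer_, nrow = length(smiles), ncol = FP_NBITS)
  for (i in seq_along(graphs)) {
    if (!is.null(graphs[[i]])) out[i, ] <- fingerprint_graph(graphs[[i]])
  }
  out
}
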