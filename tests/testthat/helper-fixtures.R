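# Shared helpers: session-cached synthetic landscapes and independent
# brute-force oracles used to cross-check the implementation.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(n, noise_sigma = 0, seed = 7, k = 20,
                           missing_frac = 0, noise_relative = FALSE,
                           tie_quantization = NULL) {
  key <- paste(n, noise_sigma, seed, k, missing_frac, noise_relative,
               paste(tie_quantization, collapse = "_"), sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    spec <- landscape_spec(n_molecules = n, noise_sigma = noise_sigma,
                           missing_frac = missing_frac,
                           noise_relative = noise_relative,
                           tie_quantization = tie_quantization)
    .fixture_cache[[key]] <- generate_pool(spec, seed = seed, k = k)
  }
  .fixture_cache[[key]]
}

# Independent atom-pair oracle: enumerate all heavy-atom pairs with
# Floyd-Warshall shortest paths (vs the implementation's walk-power
# distances) and set bits with the shared hash.
brute_force_atom_pair_fp <- function(graph, nbits = 2048L) {
  ns <- asNamespace("screenbo")
  n <- length(graph$elements)
  fp <- integer(nbits)
  if (n < 2) return(fp)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  b <- graph$bonds
  for (r in seq_len(nrow(b))) {
    D[b[r, 1], b[r, 2]] <- 1
    D[b[r, 2], b[r, 1]] <- 1
  }
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  types <- ns$atom_type_codes(graph$elements, graph$bonds)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- D[i, j]
    if (is.finite(d) && d >= 1 && d <= 3)
      fp[ns$hash_pair(types[i], types[j], as.integer(d)) + 1L] <- 1L
  }
  fp
}

# tiny deterministic pool for fast unit tests
tiny_pool <- function() {
  pool_from_smiles(c("CCO", "CCC", "c1ccccc1", "CCN", "CC(C)O", "CCCC",
                     "COC", "CCS", "CC(C)C", "OCCO"))
}
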