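# Synthetic count matrices drawn from known signatures: the
# simulate-and-recover oracle for the extraction backends.

#' Simulate a count matrix from known signatures
#'
#' Draws per-sample exposures from a symmetric Dirichlet and per-sample
#' event counts from a Poisson, then samples category counts from the
#' exposure-weighted signature mixture. Used to test that extraction
#' recovers planted signatures.
#'
#' @param signatures A signatures-by-categories matrix with rows on the
#'   simplex.
#' @param n_samples Number of samples.
#' @param mean_events Mean events per sample (Poisson).
#' @param dirichlet_alpha Symmetric Dirichlet concentration of the
#'   exposures.
#' @param seed RNG seed.
#' @return A list: `counts` (wide tibble, samples x categories),
#'   `exposures` (true exposure matrix).
#' @export
simulate_signature_matrix <- function(signatures, n_samples = 200,
                                      mean_events = 300,
                                      dirichlet_alpha = 0.8, seed = 1) {
  k <- nrow(signatures); K <- ncol(signatures)
  set.seed(seed)
  expo <- matrix(rgamma(n_samples * k, shape = dirichlet_alpha), n_samples, k)
  expo <- simplex_rows(expo)
  counts <- matrix(0L, n_samples, K)
  for (j in seq_len(n_samples)) {
    nj <- rpois(1, mean_events)
    p <- as.numeric(expo[j, ] %*% signatures)
    counts[j, ] <- as.integer(stats::rmultinom(1, nj, p))
  }
  rownames(counts) <- sprintf("S%03d", seq_len(n_samples))
  colnames(counts) <- colnames(signatures) %||% sprintf("cat%02d", seq_len(K))
  rownames(expo) <- rownames(counts)
  list(counts = matrix_to_tibble(counts), exposures = expo)
}
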