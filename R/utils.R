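# Internal helpers shared across modules.

# Strip an optional "chr" prefix so "chr1" and "1" refer to the same thing.
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

# Convert a samples-by-categories tibble (first column `sample`) to a named
# numeric matrix, or pass a matrix through.
as_count_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!"sample" %in% names(x)) {
    abort("expected a `sample` column in the count table")
  }
  m <- as.matrix(x[setdiff(names(x), "sample")])
  rownames(m) <- as.character(x$sample)
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m) {
  dplyr::bind_cols(
    tibble(sample = rownames(m) %||% character(nrow(m))),
    as_tibble(m, .name_repair = "minimal")
  )
}

# Cosine similarity between two non-negative vectors; zero vectors give 0.
#' Cosine similarity between two category vectors
#'
#' Standard cosine similarity \eqn{a \cdot b / (\|a\| \|b\|)}, used to compare
#' feature-matrix columns or signature vectors. A zero vector yields 0.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A value in `[0, 1]` for non-negative inputs.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1))
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Row-normalize a non-negative matrix to the simplex; all-zero rows stay zero.
simplex_rows <- function(m) {
  rs <- rowSums(m)
  ok <- rs > 0
  m[ok, ] <- m[ok, , drop = FALSE] / rs[ok]
  m
}

# Seeded sub-seed derivation: keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
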