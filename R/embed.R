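#' Embedding backend contract and the deterministic default
#'
#' An embedding backend maps text to a fixed-length numeric vector via
#' [backend_embed()]. The default used for soft text matching is a hashed
#' character 3-gram count embedding: lowercase the text, pad with spaces,
#' count character n-grams, and accumulate each count into
#' `hash(gram) mod dim`. It is fully deterministic and network-free;
#' an API-embedding backend is a drop-in replacement.
#'
#' @param dim Vector dimension.
#' @param n N-gram length.
#' @return An `ngram_embedding_backend`.
#' @export
ngram_embedding_backend <- function(dim = 512, n = 3) {
  if (!is_count(dim) || !is_count(n)) {
    stop_litmine("ngram_embedding_backend: dim and n must be positive integers", "config")
  }
  structure(list(dim = as.integer(dim), n = as.integer(n)),
            class = c("ngram_embedding_backend", "litmine_embedding"),
            deterministic = TRUE)
}

#' @rdname ngram_embedding_backend
#' @param backend An embedding backend.
#' @param text A single string.
#' @export
backend_embed <- function(backend, text) {
  UseMethod("backend_embed")
}

# character n-grams of a normalised string (single leading/trailing pad)
char_ngrams <- function(text, n) {
  s <- paste0(" ", tolower(trimws(text)), " ")
  nc <- nchar(s)
  if (nc < n) return(character())
  vapply(seq_len(nc - n + 1L), function(i) substr(s, i, i + n - 1L), character(1))
}

#' @export
backend_embed.ngram_embedding_backend <- function(backend, text) {
  stopifnot(is_string(text))
  v <- numeric(backend$dim)
  grams <- char_ngrams(text, backend$n)
  for (g in grams) {
    idx <- fnv1a(g) %% backend$dim + 1L
    v[idx] <- v[idx] + 1
  }
  v
}

#' Cosine similarity between two numeric vectors
#'
#' Returns 0 (with a warning) when either vector has zero norm.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warn("cosine_similarity: zero-norm vector; returning 0")
    return(0)
  }
  sum(x * y) / (nx * ny)
}
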