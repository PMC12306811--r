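#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Classed abort so callers can distinguish configuration vs parse vs validation
# failures programmatically.
stop_litmine <- function(message, class, ...) {
  abort(message, class = c(paste0("litmine_", class), "litmine_error"), ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_nonempty_string <- function(x) is_string(x) && nzchar(trimws(x))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

as_date_strict <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L) stop_litmine(sprintf("%s must be a single date", what), "config")
  d
}

# 32-bit FNV-1a over UTF-8 bytes, folded into [0, 2^31 - 1] so derived seeds
# stay valid R integers.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keeps h a plain double
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # multiply by the FNV prime mod 2^32 in two 16-bit halves so the
    # intermediate products stay exactly representable as doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Vectorized polynomial hash for long texts (prompt-level seeding); fnv1a
# stays for short strings where its byte loop is cheap. Both fold into
# [0, 2^31 - 1].
text_hash <- function(x) {
  codes <- utf8ToInt(enc2utf8(x))
  n <- length(codes)
  if (!n) return(0L)
  w <- 13^((seq_len(n) - 1L) %% 8L)
  as.integer((sum(codes * w) + n * 131071) %% 2147483647)
}

# Deterministic child seed from a parent seed and any number of string/number
# tags; always below 2^31.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  text_hash(tag)
}

# Lowercase word tokens; the unit of matching for the offline boolean engine.
tokenize <- function(text) {
  text <- tolower(text)
  toks <- unlist(strsplit(text, "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

# Light suffix stemmer, off by default in the boolean engine.
stem_tokens <- function(tokens) {
  out <- sub("(ing|ed|es)$", "", tokens)
  out <- sub("(?<=[a-z]{3})s$", "", out, perl = TRUE)
  out
}

# TRUE iff `phrase` tokens occur as a contiguous subsequence of `tokens`.
contains_phrase <- function(tokens, phrase) {
  np <- length(phrase)
  if (np == 0L) return(FALSE)
  if (np == 1L) return(phrase %in% tokens)
  n <- length(tokens)
  if (n < np) return(FALSE)
  starts <- which(tokens == phrase[[1L]])
  starts <- starts[starts <= n - np + 1L]
  for (s in starts) {
    if (all(tokens[s:(s + np - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

compact_chr <- function(x) x[nzchar(trimws(x))]

# Fenced-JSON extraction: backends answer with a ```json block (or bare JSON).
extract_json_payload <- function(text) {
  m <- regmatches(text, regexpr("```(json)?\\s*\\n[\\s\\S]*?\\n\\s*```", text, perl = TRUE))
  if (length(m) == 1L && nzchar(m)) {
    inner <- sub("^```(json)?\\s*\\n", "", m, perl = TRUE)
    inner <- sub("\\n\\s*```$", "", inner, perl = TRUE)
    return(inner)
  }
  trimws(text)
}

parse_backend_json <- function(text, context) {
  payload <- extract_json_payload(text)
  parsed <- tryCatch(
    jsonlite::fromJSON(payload, simplifyVector = FALSE),
    error = function(e) NULL
  )
  if (is.null(parsed)) {
    stop_litmine(
      sprintf("could not parse backend output as JSON (%s)", context),
      "parse_error",
      raw_output = text
    )
  }
  parsed
}
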