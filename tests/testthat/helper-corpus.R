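# Shared fixtures, built in code. Corpora are cached per configuration so a
# given fixture is generated once per test run.

.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(n_reviews = 4, included_per_review = 5,
                          distractors_per_review = 45, overlap_rate = 0.3,
                          seed = 101, vocab_size = 400) {
  key <- paste(n_reviews, included_per_review, distractors_per_review,
               overlap_rate, seed, vocab_size, sep = "_")
  if (is.null(.corpus_cache[[key]])) {
    .corpus_cache[[key]] <- generate_corpus(synthetic_config(
      n_reviews = n_reviews, included_per_review = included_per_review,
      distractors_per_review = distractors_per_review,
      overlap_rate = overlap_rate, seed = seed, vocab_size = vocab_size
    ))
  }
  .corpus_cache[[key]]
}

# Independent brute-force oracle for boolean evaluation: per document,
# evaluate the query as a logical predicate over phrase containment,
# recursing the tree directly (no sets, no masks).
brute_force_matches <- function(query, corpus) {
  words <- function(text) {
    w <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
    w[nzchar(w)]
  }
  phrase_in <- function(doc_words, phrase_words) {
    np <- length(phrase_words)
    nd <- length(doc_words)
    if (np == 0 || nd < np) return(FALSE)
    any(vapply(seq_len(nd - np + 1), function(s) {
      identical(doc_words[s:(s + np - 1)], phrase_words)
    }, logical(1)))
  }
  doc_match <- function(node, doc_words) {
    if (node$op == "term") {
      return(phrase_in(doc_words, words(node$text)))
    }
    vals <- vapply(node$children, doc_match, logical(1), doc_words = doc_words)
    if (node$op == "and") all(vals) else any(vals)
  }
  ids <- names(corpus$studies)
  ids[vapply(ids, function(i) {
    s <- corpus$studies[[i]]
    doc_match(query, words(paste(s$title, s$abstract)))
  }, logical(1))]
}

# random query tree over a term pool, for round-trip and oracle properties
random_query <- function(terms, depth = 3, seed = 1) {
  withr::with_seed(seed, .random_query_node(terms, depth))
}

.random_query_node <- function(terms, depth) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(bq_term(sample(terms, 1)))
  }
  n_children <- sample(2:3, 1)
  children <- lapply(seq_len(n_children), function(i) {
    .random_query_node(terms, depth - 1)
  })
  if (stats::runif(1) < 0.5) bq_and(children) else bq_or(children)
}

# planted review-level + study-specific terms of one review
review_planted_terms <- function(corpus, review_id) {
  truth <- corpus$inclusion_truth[[review_id]]
  unique(unlist(lapply(corpus$studies[truth], function(s) {
    c(s$planted_terms$population, s$planted_terms$intervention)
  }), use.names = FALSE))
}

# Analytic expected recall at truth size for noisy-oracle screening:
# distractors score exactly -1 (all-NO), a truth study drops to -1 only if
# all C of its YES labels flip (probability q = eps^C); ties at -1 break by
# ascending study id. P(truth t ranked in top |truth|) =
# (1 - q) + q * P(Binom(g_t, q) >= d_t), with d_t the number of pool
# distractors with id below t and g_t the number of truth ids above t.
expected_noisy_recall <- function(corpus, review_id, pool, eps) {
  review <- corpus$reviews[[review_id]]
  cc <- length(review_criteria(review))
  q <- eps^cc
  truth <- intersect(pool, corpus$inclusion_truth[[review_id]])
  distractors <- setdiff(pool, truth)
  p_top <- vapply(truth, function(t) {
    d_t <- sum(distractors < t)
    g_t <- sum(truth > t)
    (1 - q) + q * (1 - stats::pbinom(d_t - 1, g_t, q))
  }, numeric(1))
  mean(p_top)
}

# direct arithmetic score map, independent of label_to_score
direct_score <- function(labels) {
  map <- c(YES = 1, PARTIAL = 0.5, UNCERTAIN = 0, NO = -1)
  mean(unname(map[labels]))
}

# fenced-JSON eligibility analysis for injection through a mock backend
analysis_json <- function(labels) {
  body <- jsonlite::toJSON(
    lapply(labels, function(l) list(label = l, rationale = "injected")),
    auto_unbox = TRUE
  )
  paste0("```json\n", body, "\n```")
}
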