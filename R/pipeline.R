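#' End-to-end search pipeline for one review
#'
#' Generates a query (or an ensemble of them) from the review's PICO
#' frame through the backend, retrieves against the offline engine, and
#' scores recall against the review's ground truth.
#'
#' @param corpus A [linked_corpus()].
#' @param review_id Review to run.
#' @param backend A generative backend.
#' @param n_runs Ensemble size (1 = single query).
#' @param limit Retrieval limit (default 3000).
#' @param seed Base seed for ensemble runs.
#' @return One-row tibble: `review_id`, `n_runs`, `n_hits`, `recall`,
#'   `n_truth`; retrieved ids attached as attribute `"hits"`.
#' @export
run_search_pipeline <- function(corpus, review_id, backend, n_runs = 1,
                                limit = 3000, seed = 1) {
  review <- corpus_review(corpus, review_id)
  truth <- corpus_truth(corpus, review_id)
  if (!length(truth)) stop_litmine(sprintf("review '%s' has no truth set", review_id), "config")
  hits <- ensemble_generate(review$pico, backend, corpus, n_runs = n_runs,
                            limit = limit, seed = seed, review_id = review_id)
  out <- tibble(
    review_id = review_id, n_runs = as.integer(n_runs),
    n_hits = length(hits),
    recall = length(intersect(hits, truth)) / length(truth),
    n_truth = length(truth)
  )
  attr(out, "hits") <- hits
  out
}

#' End-to-end screening pipeline for one review
#'
#' Builds the candidate pool (primary hits from a backend-generated query,
#' topped up by single-element queries and time-constrained), assesses
#' every candidate criterion-by-criterion, ranks by final eligibility
#' score, and reports recall at the truth-set size.
#'
#' @inheritParams run_search_pipeline
#' @param pool_size Candidate-pool cap (default 2000).
#' @param assess_seed Seed forwarded to the assessing backend (used by the
#'   noisy oracle; ignored by deterministic backends).
#' @return The ranked screening tibble (see [screen_candidates()]) with
#'   attributes `"recall"` (recall at truth size) and `"pool"`.
#' @export
run_screening_pipeline <- function(corpus, review_id, backend, pool_size = 2000,
                                   limit = 3000, seed = 1, assess_seed = NULL) {
  review <- corpus_review(corpus, review_id)
  truth <- corpus_truth(corpus, review_id)
  if (!length(truth)) stop_litmine(sprintf("review '%s' has no truth set", review_id), "config")
  query <- generate_query(review$pico, backend, seed = seed, review_id = review_id)
  primary <- retrieve(query, corpus, limit = limit)
  pool <- build_candidate_pool(review, corpus, primary, pool_size = pool_size)
  ranked <- screen_candidates(review, corpus, pool, backend, seed = assess_seed)
  attr(ranked, "recall") <- recall_at_truth_size(ranked$study_id, truth)
  attr(ranked, "pool") <- pool
  ranked
}
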