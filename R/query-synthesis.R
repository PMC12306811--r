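#' Per-study keyword sets for query synthesis
#'
#' For each ground-truth study a backend extracts up to `M = 10`
#' population keywords and up to 10 intervention keywords; these per-study
#' sets are the building blocks of the aggregated search query. Term lists
#' are whitespace-trimmed, deduplicated, and truncated to 10.
#'
#' @param source_study_id Identifier of the study the terms came from.
#' @param population_terms,intervention_terms Character vectors (1..10
#'   non-empty strings each after normalisation).
#' @return A `term_set` object.
#' @export
term_set <- function(source_study_id, population_terms, intervention_terms) {
  norm <- function(x, what) {
    x <- unique(trimws(as.character(x)))
    x <- x[nzchar(x)]
    if (!length(x)) {
      stop_litmine(
        sprintf("term_set: empty %s list for study '%s'", what, source_study_id),
        "assembly", study_id = source_study_id
      )
    }
    utils::head(x, 10L)
  }
  structure(
    list(
      source_study_id = source_study_id,
      population_terms = norm(population_terms, "population"),
      intervention_terms = norm(intervention_terms, "intervention")
    ),
    class = "term_set"
  )
}

#' Extract per-study search terms through a backend
#'
#' Prompts the backend with the study's title and abstract and parses its
#' fenced-JSON answer into a [term_set()]. The corpus-bound oracle backend
#' returns the generator-planted terms exactly.
#'
#' @param study A [study_record()] with title and abstract.
#' @param backend A generative backend.
#' @param seed Optional seed forwarded to the backend.
#' @return A [term_set()].
#' @export
extract_terms <- function(study, backend, seed = NULL) {
  stopifnot(inherits(study, "study_record"))
  prompt <- render_prompt("term_extraction", list(
    study_id = study$study_id, title = study$title, abstract = study$abstract
  ))
  raw <- backend_complete(backend, prompt, seed = seed)
  parsed <- parse_backend_json(raw, sprintf("term extraction for study '%s'", study$study_id))
  pop <- unlist(parsed$population, use.names = FALSE)
  int <- unlist(parsed$intervention, use.names = FALSE)
  if (is.null(pop) || is.null(int)) {
    stop_litmine(
      sprintf("term extraction for study '%s': missing population/intervention group",
              study$study_id),
      "parse_error", raw_output = raw
    )
  }
  term_set(study$study_id, pop, int)
}

#' Assemble the aggregated boolean query from per-study term sets
#'
#' Builds `S = SP AND SI` where `SP` is the OR over studies of that
#' study's population terms joined by the inner connective (AND by
#' default), and `SI` likewise for intervention terms. With the default
#' inner connective this is the aggregation rule exactly: each study
#' contributes the conjunction of its own terms, and studies are unioned.
#' `inner_connective = "or"` is offered because conjoining up to ten terms
#' is very restrictive against real abstracts.
#'
#' @param termsets Non-empty list of [term_set()]s.
#' @param inner_connective `"and"` (default) or `"or"`.
#' @return A [bq_and()] query `S`.
#' @export
assemble_query <- function(termsets, inner_connective = c("and", "or")) {
  inner_connective <- match.arg(inner_connective)
  if (!length(termsets)) stop_litmine("assemble_query: no term sets", "assembly")
  stopifnot(all(vapply(termsets, inherits, logical(1), what = "term_set")))
  inner <- if (inner_connective == "and") bq_and else bq_or
  group <- function(terms) inner(lapply(terms, bq_term))
  sp <- bq_or(lapply(termsets, function(ts) group(ts$population_terms)))
  si <- bq_or(lapply(termsets, function(ts) group(ts$intervention_terms)))
  bq_and(sp, si)
}

#' Recall-based query quality filter
#'
#' Measures the query's recall against a review's ground-truth study set
#' on the offline engine and keeps it iff recall >= `threshold` (queries
#' with recall below the threshold are dropped as poorly generated; the
#' boundary is inclusive-keep).
#'
#' @param query A `bool_query`.
#' @param corpus A [linked_corpus()].
#' @param truth Non-empty character vector of ground-truth study ids.
#' @param threshold Recall threshold (default 0.2).
#' @return One-row tibble: `keep`, `recall`, `n_truth`, `n_matched`.
#' @export
filter_by_recall <- function(query, corpus, truth, threshold = 0.2) {
  if (!length(truth)) {
    stop_litmine("filter_by_recall: empty truth set gives undefined recall", "config")
  }
  matched <- evaluate_query(query, corpus)
  hits <- length(intersect(matched, truth))
  recall <- hits / length(truth)
  tibble(
    keep = recall >= threshold, recall = recall,
    n_truth = length(truth), n_matched = length(matched)
  )
}

#' Generate a boolean query from a PICO frame through a backend
#'
#' Prompts the backend with the review's PICO elements, parses the
#' answered population/intervention keyword groups, and assembles them as
#' a single-study term-set pair under the aggregation rule. A missing
#' intervention (or population) group is a generation error carrying the
#' raw output.
#'
#' @param pico A [pico_frame()].
#' @param backend A generative backend.
#' @param seed Optional seed forwarded to the backend.
#' @param review_id Identifier written into the prompt context (defaults
#'   to a placeholder for ad-hoc frames).
#' @param inner_connective Passed to [assemble_query()].
#' @return A `bool_query`.
#' @export
generate_query <- function(pico, backend, seed = NULL, review_id = "adhoc",
                           inner_connective = "and") {
  stopifnot(inherits(pico, "pico_frame"))
  prompt <- render_prompt("search_query", list(
    review_id = review_id,
    population = pico$population, intervention = pico$intervention,
    comparator = pico$comparator, outcome = pico$outcome
  ))
  raw <- backend_complete(backend, prompt, seed = seed)
  parsed <- parse_backend_json(raw, sprintf("query generation for review '%s'", review_id))
  pop <- unlist(parsed$population, use.names = FALSE)
  int <- unlist(parsed$intervention, use.names = FALSE)
  if (is.null(pop) || !length(pop) || is.null(int) || !length(int)) {
    stop_litmine(
      sprintf("query generation for review '%s': missing keyword group", review_id),
      "parse_error", raw_output = raw
    )
  }
  assemble_query(list(term_set(review_id, pop, int)),
                 inner_connective = inner_connective)
}

#' Ensemble query generation with union of retrievals
#'
#' Samples `n_runs` queries from the backend under run-indexed seeds
#' (`seed + run` for run 0..n_runs-1), retrieves for each, and returns the
#' per-run result lists concatenated in run order with duplicates removed
#' keeping the first occurrence. Runs whose output fails to parse are
#' skipped with a warning; the call errors only if every run fails.
#' Ensemble recall is therefore non-decreasing in `n_runs`.
#'
#' @inheritParams generate_query
#' @param corpus A [linked_corpus()].
#' @param n_runs Number of sampled queries (default 10).
#' @param limit Per-run retrieval limit (default 3000).
#' @return Character vector of study ids (aggregated, deduplicated).
#' @export
ensemble_generate <- function(pico, backend, corpus, n_runs = 10, limit = 3000,
                              seed = 1, review_id = "adhoc",
                              inner_connective = "and") {
  if (!is_count(n_runs)) stop_litmine("ensemble_generate: n_runs must be >= 1", "config")
  all_hits <- character()
  failures <- 0L
  for (run in seq_len(n_runs) - 1L) {
    q <- tryCatch(
      generate_query(pico, backend, seed = seed + run, review_id = review_id,
                     inner_connective = inner_connective),
      litmine_parse_error = function(e) {
        warn(sprintf("ensemble run %d skipped: %s", run, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(q)) {
      failures <- failures + 1L
      next
    }
    all_hits <- c(all_hits, retrieve(q, corpus, limit = limit))
  }
  if (failures == n_runs) {
    stop_litmine("ensemble_generate: every run failed to produce a query", "parse_error")
  }
  unique(all_hits)
}
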