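.eligibility_labels <- c(YES = 1, PARTIAL = 0.5, UNCERTAIN = 0, NO = -1)

#' Criterion label scores and their aggregation
#'
#' Criterion-level eligibility labels map to numeric scores — YES 1,
#' PARTIAL 0.5, UNCERTAIN 0, NO -1 — and a study's final eligibility score
#' is the arithmetic mean of its criterion scores, so it always lies in
#' `[-1, 1]` with the extremes reached exactly for all-NO / all-YES.
#' "Partially Yes" is the same label as PARTIAL.
#'
#' @param label One of `"YES"`, `"PARTIAL"`, `"UNCERTAIN"`, `"NO"`.
#' @return `label_to_score()` the numeric score; `aggregate_score()` the
#'   mean of the assessment scores.
#' @export
#' @examples
#' label_to_score("PARTIAL")
#' aggregate_score(data.frame(label = c("YES", "PARTIAL", "UNCERTAIN", "NO")))
label_to_score <- function(label) {
  if (!is_string(label) || !label %in% names(.eligibility_labels)) {
    stop_litmine(
      sprintf("unknown eligibility label '%s' (expected YES/PARTIAL/UNCERTAIN/NO)",
              paste(label, collapse = ", ")),
      "label"
    )
  }
  unname(.eligibility_labels[[label]])
}

#' @rdname label_to_score
#' @param assessments A data frame with a `label` column (one row per
#'   criterion), or a character vector of labels.
#' @export
aggregate_score <- function(assessments) {
  labels <- if (is.data.frame(assessments)) assessments$label else assessments
  if (!length(labels)) {
    stop_litmine("aggregate_score: no criterion assessments", "aggregation")
  }
  mean(vapply(as.character(labels), label_to_score, numeric(1)))
}

#' Assess one study against a review's criteria
#'
#' Renders the eligibility prompt (criteria as JSON, study title and
#' abstract), asks the backend for one (label, rationale) pair per
#' criterion, and aggregates the criterion scores into the final
#' eligibility score. A criterion whose answer is missing or unparseable
#' degrades to UNCERTAIN (score 0) with rationale `"unparsed"` and a
#' warning, keeping the ranking total rather than failing the study.
#'
#' @param criteria Non-empty list of [criterion()] objects.
#' @param study A [study_record()].
#' @param backend A generative backend.
#' @param review_id Review identifier written into the prompt context.
#' @param seed Optional seed forwarded to the backend.
#' @return An `eligibility_result`: list with `study_id`, `assessments`
#'   (tibble: element, criterion, role, label, rationale, score) and
#'   `final_score`.
#' @export
assess_study <- function(criteria, study, backend, review_id = "adhoc", seed = NULL) {
  if (!length(criteria)) stop_litmine("assess_study: criteria must be non-empty", "config")
  stopifnot(inherits(study, "study_record"))
  crit_json <- jsonlite::toJSON(
    lapply(criteria, function(cr) list(element = cr$element, text = cr$text, role = cr$role)),
    auto_unbox = TRUE
  )
  prompt <- render_prompt("eligibility", list(
    review_id = review_id, study_id = study$study_id,
    criteria = as.character(crit_json),
    title = study$title, abstract = study$abstract
  ))
  raw <- backend_complete(backend, prompt, seed = seed)
  answers <- tryCatch(
    parse_backend_json(raw, sprintf("eligibility for study '%s'", study$study_id)),
    litmine_parse_error = function(e) list()
  )
  n <- length(criteria)
  labels <- character(n)
  rationales <- character(n)
  n_unparsed <- 0L
  for (i in seq_len(n)) {
    a <- if (i <= length(answers)) answers[[i]] else NULL
    lab <- a$label %||% NA_character_
    if (!is_string(lab) || !lab %in% names(.eligibility_labels)) {
      labels[i] <- "UNCERTAIN"
      rationales[i] <- "unparsed"
      n_unparsed <- n_unparsed + 1L
    } else {
      labels[i] <- lab
      rationales[i] <- as.character(a$rationale %||% "")
    }
  }
  if (n_unparsed > 0L) {
    warn(sprintf("assess_study: %d of %d criterion answers unparsed for study '%s'; labeled UNCERTAIN",
                 n_unparsed, n, study$study_id))
  }
  assessments <- tibble(
    element = vapply(criteria, function(cr) cr$element, character(1)),
    criterion = vapply(criteria, function(cr) cr$text, character(1)),
    role = vapply(criteria, function(cr) cr$role, character(1)),
    label = labels,
    rationale = rationales,
    score = vapply(labels, label_to_score, numeric(1))
  )
  structure(
    list(study_id = study$study_id, assessments = assessments,
         final_score = mean(assessments$score)),
    class = "eligibility_result"
  )
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("<eligibility_result> study %s, final score %.3f\n",
              x$study_id, x$final_score))
  print(x$assessments[, c("element", "label", "score")])
  invisible(x)
}

#' Build the candidate pool for screening a review
#'
#' Primary (query-derived) hits come first, time-constrained to predate
#' the review. If fewer than `pool_size` remain, the pool is topped up
#' with deduplicated hits from single-element queries over the review's
#' other PICO elements — population-only, then intervention-only, then
#' outcome-only — until `pool_size` or exhaustion. An undersized pool is
#' returned as-is with an informational message.
#'
#' @param review A [review_topic()].
#' @param corpus A [linked_corpus()].
#' @param primary_hits Ordered character vector of study ids.
#' @param pool_size Maximum pool size (default 2000).
#' @return Ordered character vector of study ids, all predating the
#'   review, each id at most once (primary position kept).
#' @export
build_candidate_pool <- function(review, corpus, primary_hits, pool_size = 2000) {
  if (!is_count(pool_size)) stop_litmine("build_candidate_pool: pool_size must be >= 1", "config")
  timely <- function(ids) {
    recs <- corpus$studies[intersect(ids, names(corpus$studies))]
    recs <- withCallingHandlers(
      apply_time_constraint(review, unname(recs)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    vapply(recs, function(s) s$study_id, character(1))
  }
  pool <- unique(timely(primary_hits))
  if (length(pool) < pool_size) {
    for (element in c("population", "intervention", "outcome")) {
      text <- review$pico[[element]]
      if (!nzchar(trimws(text))) next
      terms <- compact_chr(trimws(strsplit(text, ";")[[1]]))
      if (!length(terms)) next
      q <- bq_or(lapply(terms, bq_term))
      fill <- timely(retrieve(q, corpus, limit = pool_size))
      pool <- unique(c(pool, fill))
      if (length(pool) >= pool_size) break
    }
  }
  if (length(pool) < pool_size) {
    inform(sprintf("candidate pool for review '%s' undersized: %d of %d",
                   review$review_id, length(pool), pool_size))
  }
  utils::head(pool, pool_size)
}

#' Screen and rank a candidate pool
#'
#' `screen_candidates()` assesses every candidate with [assess_study()]
#' and returns the ranked tibble; `rank_candidates()` orders eligibility
#' results by descending final score with ties broken by ascending
#' `study_id` (a total, deterministic order, so recall at K is
#' well-defined).
#'
#' @param review A [review_topic()] (criteria taken from
#'   [review_criteria()]).
#' @param corpus A [linked_corpus()].
#' @param pool Character vector of candidate study ids.
#' @param backend A generative backend.
#' @param seed Optional seed forwarded to the backend.
#' @return A tibble with one row per candidate: `rank`, `study_id`,
#'   `final_score`, one `label_<element><i>` column per criterion, and a
#'   `rationales` JSON column. The unranked `eligibility_result` objects
#'   are attached as attribute `"results"`.
#' @export
screen_candidates <- function(review, corpus, pool, backend, seed = NULL) {
  criteria <- review_criteria(review)
  if (!length(criteria)) stop_litmine("screen_candidates: review has no criteria", "config")
  results <- lapply(pool, function(sid) {
    assess_study(criteria, corpus_study(corpus, sid), backend,
                 review_id = review$review_id, seed = seed)
  })
  ranked <- rank_candidates(results)
  out <- as_tibble(ranked)
  attr(out, "results") <- results
  out
}

#' @rdname screen_candidates
#' @param results List of `eligibility_result` objects.
#' @export
rank_candidates <- function(results) {
  if (!length(results)) return(list())
  scores <- vapply(results, function(r) r$final_score, numeric(1))
  ids <- vapply(results, function(r) r$study_id, character(1))
  ord <- order(-scores, ids, method = "radix")
  structure(results[ord], class = "ranked_eligibility")
}

#' @export
as_tibble.ranked_eligibility <- function(x, ...) {
  rows <- lapply(seq_along(x), function(i) {
    r <- x[[i]]
    labels <- as.list(r$assessments$label)
    names(labels) <- sprintf("label_%s%d", r$assessments$element,
                             seq_along(labels))
    dplyr::bind_cols(
      tibble(rank = i, study_id = r$study_id, final_score = r$final_score),
      as_tibble(labels),
      tibble(rationales = as.character(
        jsonlite::toJSON(r$assessments$rationale, auto_unbox = FALSE)
      ))
    )
  })
  dplyr::bind_rows(rows)
}

#' Stratify eligibility results into score bands
#'
#' Partitions results into the three bands used to compare model
#' assessments with expert decisions: `[-1, -0.5]` (predicted False),
#' `(-0.5, 0.75)` (middle), `[0.75, 1]` (predicted True). Every result
#' falls in exactly one band.
#'
#' @param results List of `eligibility_result`s (or a `ranked_eligibility`).
#' @return A tibble: `study_id`, `final_score`, `band` (factor with levels
#'   `predicted_false`, `middle`, `predicted_true`).
#' @export
stratify_by_score <- function(results) {
  scores <- vapply(results, function(r) r$final_score, numeric(1))
  band <- ifelse(scores >= 0.75, "predicted_true",
                 ifelse(scores <= -0.5, "predicted_false", "middle"))
  tibble(
    study_id = vapply(results, function(r) r$study_id, character(1)),
    final_score = scores,
    band = factor(band, levels = c("predicted_false", "middle", "predicted_true"))
  )
}
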