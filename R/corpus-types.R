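#' PICO frame for a research question
#'
#' The structured framing of a clinical research question: Population,
#' Intervention, Comparator, Outcome. Population and intervention must be
#' non-empty for any review that feeds query synthesis; comparator and
#' outcome may be empty strings.
#'
#' @param population,intervention,comparator,outcome Single strings.
#'   Multi-term fields may list terms separated by `"; "`.
#' @return A `pico_frame` object (named list).
#' @export
#' @examples
#' pico_frame("adults with atrial fibrillation", "warfarin")
pico_frame <- function(population, intervention, comparator = "", outcome = "") {
  if (!is_nonempty_string(population)) {
    stop_litmine("pico_frame: population must be a non-empty string", "config")
  }
  if (!is_nonempty_string(intervention)) {
    stop_litmine("pico_frame: intervention must be a non-empty string", "config")
  }
  structure(
    list(
      population = population, intervention = intervention,
      comparator = comparator %||% "", outcome = outcome %||% ""
    ),
    class = "pico_frame"
  )
}

#' Eligibility criterion
#'
#' A single inclusion or exclusion criterion, categorised into exactly one
#' PICO element. Exclusion-role criteria are phrased so that a YES
#' assessment still means "the study satisfies this requirement"; the
#' negation lives in the assessor prompt, keeping score aggregation
#' sign-free.
#'
#' @param element One of `"P"`, `"I"`, `"C"`, `"O"`.
#' @param text Non-empty criterion text.
#' @param role `"inclusion"` or `"exclusion"`.
#' @return A `criterion` object.
#' @export
criterion <- function(element, text, role = "inclusion") {
  element <- match.arg(element, c("P", "I", "C", "O"))
  role <- match.arg(role, c("inclusion", "exclusion"))
  if (!is_nonempty_string(text)) {
    stop_litmine("criterion: text must be a non-empty string", "config")
  }
  structure(list(element = element, text = text, role = role), class = "criterion")
}

#' Review topic
#'
#' A systematic-review research question: title/abstract, PICO frame,
#' eligibility criteria, a topic-area tag, and the review's publication
#' date (the cutoff for candidate studies).
#'
#' @param review_id Unique opaque identifier.
#' @param title,abstract Text.
#' @param pico A [pico_frame()].
#' @param criteria List of [criterion()] objects; may be empty, but must be
#'   non-empty for screening (see [review_criteria()]).
#' @param topic_area Categorical tag.
#' @param pub_date Calendar date (anything `as.Date()` accepts).
#' @return A `review_topic` object.
#' @export
review_topic <- function(review_id, title, abstract, pico, criteria = list(),
                         topic_area = "general", pub_date) {
  if (!is_nonempty_string(review_id)) {
    stop_litmine("review_topic: review_id must be a non-empty string", "config")
  }
  stopifnot(inherits(pico, "pico_frame"))
  structure(
    list(
      review_id = review_id, title = title, abstract = abstract,
      pico = pico, criteria = criteria, topic_area = topic_area,
      pub_date = as_date_strict(pub_date, "review pub_date")
    ),
    class = "review_topic"
  )
}

#' Citation or registry record
#'
#' A candidate study: either a publication (title/abstract, optional full
#' text and table text, optional `nct_link` and, for synthetic linked
#' studies, the registry-derived structured truth) or a trial-registry
#' record carrying `registry_truth`.
#'
#' @param study_id Opaque identifier (synthetic corpora use PMID-like
#'   8-digit strings for publications).
#' @param kind `"publication"` or `"trial_registry"`.
#' @param title,abstract Text.
#' @param full_text Optional full-text string.
#' @param table_text Optional character vector of table blocks.
#' @param pub_date Calendar date, or `NA` (records without a date are
#'   skipped by the time constraint with a warning).
#' @param nct_link Optional `"NCT\\d{8}"` registry identifier.
#' @param registry_truth Optional [registry_data()].
#' @param planted_terms Optional list with `population`/`intervention`
#'   character vectors; set by the synthetic generator and read by the
#'   oracle backend.
#' @return A `study_record` object.
#' @export
study_record <- function(study_id, kind = c("publication", "trial_registry"),
                         title, abstract, full_text = NULL, table_text = NULL,
                         pub_date = NA, nct_link = NULL, registry_truth = NULL,
                         planted_terms = NULL) {
  kind <- match.arg(kind)
  if (!is_nonempty_string(study_id)) {
    stop_litmine("study_record: study_id must be a non-empty string", "config")
  }
  if (!is.null(registry_truth)) stopifnot(inherits(registry_truth, "registry_data"))
  pd <- if (length(pub_date) == 1L && is.na(pub_date)) as.Date(NA) else as_date_strict(pub_date, "study pub_date")
  structure(
    list(
      study_id = study_id, kind = kind, title = title, abstract = abstract,
      full_text = full_text, table_text = table_text, pub_date = pd,
      nct_link = nct_link, registry_truth = registry_truth,
      planted_terms = planted_terms
    ),
    class = "study_record"
  )
}

#' Structured registry truth for a trial
#'
#' The structured fields a ClinicalTrials.gov record carries for a trial:
#' conditions, interventions, enrollment, study type, arm designs,
#' participant measures, and outcome results. In synthetic corpora these
#' values are embedded verbatim into the linked publication's pseudo full
#' text and table text, so extraction is verifiable round-trip.
#'
#' @param conditions,interventions Character vectors.
#' @param enrollment Non-negative integer.
#' @param study_type Text, e.g. `"INTERVENTIONAL"`.
#' @param arms List of [arm_record()]; labels must be unique.
#' @param participant_measures List of participant-measure truth entries
#'   (see [participant_stats_request()] for the request side).
#' @param outcome_results List of trial-result truth entries.
#' @return A `registry_data` object.
#' @export
registry_data <- function(conditions = character(), interventions = character(),
                          enrollment = 0L, study_type = "INTERVENTIONAL",
                          arms = list(), participant_measures = list(),
                          outcome_results = list()) {
  if (!is.numeric(enrollment) || length(enrollment) != 1L || is.na(enrollment) || enrollment < 0) {
    stop_litmine("registry_data: enrollment must be a non-negative number", "config")
  }
  labels <- vapply(arms, function(a) a$label, character(1))
  if (anyDuplicated(labels)) {
    stop_litmine(
      sprintf("registry_data: duplicate arm label '%s'", labels[duplicated(labels)][1]),
      "validation"
    )
  }
  structure(
    list(
      conditions = as.character(conditions),
      interventions = as.character(interventions),
      enrollment = as.integer(enrollment), study_type = study_type,
      arms = arms, participant_measures = participant_measures,
      outcome_results = outcome_results
    ),
    class = "registry_data"
  )
}

#' Trial arm design
#'
#' One participant group of a trial: a unique label, an arm type (e.g.
#' `"EXPERIMENTAL"`), a free-text description, and the interventions
#' administered to the group.
#'
#' @param label Non-empty label, unique within a study.
#' @param arm_type Text.
#' @param description Text.
#' @param intervention_names Character vector.
#' @return An `arm_record` object.
#' @export
arm_record <- function(label, arm_type = "EXPERIMENTAL", description = "",
                       intervention_names = character()) {
  if (!is_nonempty_string(label)) {
    stop_litmine("arm_record: label must be a non-empty string", "config")
  }
  structure(
    list(
      label = label, arm_type = arm_type, description = description,
      intervention_names = as.character(intervention_names)
    ),
    class = "arm_record"
  )
}

#' Linked corpus
#'
#' The offline stand-in for a bibliographic database: a set of review
#' topics, a pool of candidate studies, and the ground-truth inclusion map
#' giving, for each review, the identifiers of its N included studies.
#'
#' @param reviews List of [review_topic()] objects (unique ids).
#' @param studies List of [study_record()] objects (unique ids).
#' @param inclusion_truth Named list: `review_id` -> character vector of
#'   included `study_id`s; every id must exist in `studies`.
#' @return A `linked_corpus` object.
#' @export
linked_corpus <- function(reviews, studies, inclusion_truth) {
  rids <- vapply(reviews, function(r) r$review_id, character(1))
  sids <- vapply(studies, function(s) s$study_id, character(1))
  if (anyDuplicated(rids)) stop_litmine("linked_corpus: duplicate review_id", "validation")
  if (anyDuplicated(sids)) stop_litmine("linked_corpus: duplicate study_id", "validation")
  missing <- setdiff(unlist(inclusion_truth, use.names = FALSE), sids)
  if (length(missing)) {
    stop_litmine(
      sprintf("linked_corpus: inclusion_truth references unknown studies: %s",
              paste(utils::head(missing, 3), collapse = ", ")),
      "validation"
    )
  }
  names(reviews) <- rids
  names(studies) <- sids
  structure(
    list(reviews = reviews, studies = studies, inclusion_truth = inclusion_truth),
    class = "linked_corpus"
  )
}

corpus_review <- function(corpus, review_id) {
  r <- corpus$reviews[[review_id]]
  if (is.null(r)) stop_litmine(sprintf("unknown review_id '%s'", review_id), "lookup")
  r
}

corpus_study <- function(corpus, study_id) {
  s <- corpus$studies[[study_id]]
  if (is.null(s)) stop_litmine(sprintf("unknown study_id '%s'", study_id), "lookup")
  s
}

corpus_truth <- function(corpus, review_id) {
  corpus$inclusion_truth[[review_id]] %||% character()
}

#' Criteria for screening a review
#'
#' Returns the review's explicit criteria list if present; otherwise
#' derives one criterion per non-empty PICO element (P and I always, C and
#' O when their text is non-empty).
#'
#' @param review A [review_topic()].
#' @return List of [criterion()] objects.
#' @export
review_criteria <- function(review) {
  if (length(review$criteria)) return(review$criteria)
  pico <- review$pico
  out <- list(
    criterion("P", paste("Population:", pico$population)),
    criterion("I", paste("Intervention:", pico$intervention))
  )
  if (nzchar(trimws(pico$comparator))) {
    out <- c(out, list(criterion("C", paste("Comparator:", pico$comparator))))
  }
  if (nzchar(trimws(pico$outcome))) {
    out <- c(out, list(criterion("O", paste("Outcome:", pico$outcome))))
  }
  out
}

#' @export
print.linked_corpus <- function(x, ...) {
  n_truth <- lengths(x$inclusion_truth)
  cat(sprintf(
    "<linked_corpus> %d reviews, %d studies; included per review: %s\n",
    length(x$reviews), length(x$studies),
    if (length(n_truth)) paste(range(n_truth), collapse = "-") else "0"
  ))
  invisible(x)
}

#' @export
print.pico_frame <- function(x, ...) {
  cat("<pico_frame>\n")
  for (f in c("population", "intervention", "comparator", "outcome")) {
    cat(sprintf("  %-12s %s\n", paste0(f, ":"), x[[f]]))
  }
  invisible(x)
}

#' Tabular views of a linked corpus
#'
#' `as_tibble()` on a corpus returns one row per study; `corpus_reviews()`
#' returns one row per review with its truth-set size.
#'
#' @param x A `linked_corpus`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.linked_corpus <- function(x, ...) {
  tibble(
    study_id = vapply(x$studies, function(s) s$study_id, character(1)),
    kind = vapply(x$studies, function(s) s$kind, character(1)),
    title = vapply(x$studies, function(s) s$title, character(1)),
    pub_date = as.Date(vapply(x$studies, function(s) as.character(s$pub_date), character(1))),
    has_full_text = vapply(x$studies, function(s) !is.null(s$full_text), logical(1)),
    has_registry_truth = vapply(x$studies, function(s) !is.null(s$registry_truth), logical(1))
  )
}

#' @rdname as_tibble.linked_corpus
#' @param corpus A `linked_corpus`.
#' @export
corpus_reviews <- function(corpus) {
  tibble(
    review_id = vapply(corpus$reviews, function(r) r$review_id, character(1)),
    title = vapply(corpus$reviews, function(r) r$title, character(1)),
    topic_area = vapply(corpus$reviews, function(r) r$topic_area, character(1)),
    pub_date = as.Date(vapply(corpus$reviews, function(r) as.character(r$pub_date), character(1))),
    n_truth = vapply(
      corpus$reviews,
      function(r) length(corpus_truth(corpus, r$review_id)), integer(1)
    )
  )
}

#' Restrict candidates to studies published before a review
#'
#' Applies the screening time constraint: only candidates published
#' strictly before the review's own publication date are screenable.
#' Same-day publications are excluded. Records with a missing date are
#' skipped with a warning rather than an error, since real bibliographic
#' data frequently lacks dates.
#'
#' @param review A [review_topic()].
#' @param candidates List of [study_record()]s.
#' @return The subset of `candidates` (original order) predating the
#'   review.
#' @export
apply_time_constraint <- function(review, candidates) {
  stopifnot(inherits(review, "review_topic"))
  if (!length(candidates)) return(list())
  dates <- lapply(candidates, function(s) s$pub_date)
  missing <- vapply(dates, is.na, logical(1))
  if (any(missing)) {
    warn(sprintf(
      "apply_time_constraint: skipping %d record(s) with missing pub_date",
      sum(missing)
    ))
  }
  keep <- !missing & vapply(dates, function(d) isTRUE(d < review$pub_date), logical(1))
  candidates[keep]
}
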