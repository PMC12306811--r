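#' Field specification for extensible extraction schemas
#'
#' @param name Field identifier, unique within a schema.
#' @param value_kind `"text"`, `"number"`, or `"categorical"`.
#' @param description Human-readable field definition (shown in prompts).
#' @return A `field_spec` object.
#' @export
field_spec <- function(name, value_kind = c("text", "number", "categorical"),
                       description = "") {
  value_kind <- match.arg(value_kind)
  if (!is_nonempty_string(name)) stop_litmine("field_spec: name required", "config")
  structure(list(name = name, value_kind = value_kind, description = description),
            class = "field_spec")
}

#' Default study-characteristics schema
#'
#' Conditions, interventions, enrollment, and study type — the structured
#' fields a registry record reliably carries. User-extensible: pass extra
#' [field_spec()]s to add fields.
#'
#' @param extra Optional list of additional [field_spec()]s.
#' @return Named list of `field_spec`s.
#' @export
characteristics_schema <- function(extra = list()) {
  base <- list(
    field_spec("conditions", "text", "conditions studied"),
    field_spec("interventions", "text", "interventions evaluated"),
    field_spec("enrollment", "number", "number of enrolled participants"),
    field_spec("study_type", "categorical", "registry study type")
  )
  specs <- c(base, extra)
  nm <- vapply(specs, function(f) f$name, character(1))
  if (anyDuplicated(nm)) stop_litmine("characteristics_schema: duplicate field name", "config")
  stats::setNames(specs, nm)
}

#' Extraction request objects
#'
#' The input side of the participant-statistics and trial-result
#' extraction tasks. A participant-statistics request defines the measure,
#' its parameter type and unit, and the participant groups (each with a
#' `group_id`); the result lists one value per group. A trial-result
#' request defines the outcome, group, parameter type, unit, timeframe,
#' and denominator; the result lists (value, title) pairs.
#'
#' @param measure_definition,parameter_type,unit,outcome_definition,group_definition,timeframe,denominator_unit Text.
#' @param groups List of group entries, each with `group_id`, `unit`,
#'   `value`, `definition`.
#' @param denominator_value Non-negative number (or `NA`).
#' @return A request object of class `participant_stats_request` /
#'   `trial_result_request`.
#' @export
participant_stats_request <- function(measure_definition, parameter_type, unit,
                                      groups) {
  ids <- vapply(groups, function(g) g$group_id, character(1))
  if (anyDuplicated(ids)) stop_litmine("participant_stats_request: duplicate group_id", "validation")
  structure(
    list(measure_definition = measure_definition, parameter_type = parameter_type,
         unit = unit, groups = groups),
    class = "participant_stats_request"
  )
}

#' @rdname participant_stats_request
#' @export
trial_result_request <- function(outcome_definition, group_definition,
                                 parameter_type, unit, timeframe,
                                 denominator_unit, denominator_value = NA_real_) {
  if (!is.na(denominator_value) && denominator_value < 0) {
    stop_litmine("trial_result_request: denominator_value must be >= 0", "validation")
  }
  structure(
    list(outcome_definition = outcome_definition, group_definition = group_definition,
         parameter_type = parameter_type, unit = unit, timeframe = timeframe,
         denominator_unit = denominator_unit, denominator_value = denominator_value),
    class = "trial_result_request"
  )
}

#' Truncate a study document to a token budget
#'
#' Deterministic whitespace-token truncation for long-context prompting:
#' title + abstract first, then full text, then table blocks, cut off at
#' `budget_tokens`. The abstract is therefore never dropped while any
#' full text remains. A model tokenizer can replace the whitespace count
#' via `count_tokens`.
#'
#' @param study A [study_record()].
#' @param budget_tokens Token budget (default 30000, the long-context
#'   training budget the framework assumes downstream).
#' @param count_tokens Function mapping a character vector of tokens to
#'   itself (hook point; default identity on whitespace tokens).
#' @return A single string of at most `budget_tokens` whitespace tokens.
#' @export
truncate_document <- function(study, budget_tokens = 30000,
                              count_tokens = identity) {
  if (!is_count(budget_tokens)) {
    stop_litmine("truncate_document: budget_tokens must be >= 1", "config")
  }
  pieces <- c(study$title, study$abstract, study$full_text,
              unlist(study$table_text, use.names = FALSE))
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  tokens <- count_tokens(unlist(strsplit(paste(pieces, collapse = "\n"), "\\s+")))
  tokens <- tokens[nzchar(tokens)]
  paste(utils::head(tokens, budget_tokens), collapse = " ")
}

#' Normalise a numeric field value
#'
#' Parses a predicted number from free text: strips thousands separators,
#' percent signs, and surrounding unit words, then parses the first
#' decimal number. Returns `NA` when nothing parses.
#'
#' @param x A number or string.
#' @return A numeric scalar or `NA`.
#' @export
parse_numeric_field <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is_string(x)) return(NA_real_)
  s <- trimws(x)
  s <- gsub("(?<=\\d),(?=\\d{3})", "", s, perl = TRUE) # thousands separators
  s <- gsub("%", "", s, fixed = TRUE)
  m <- regmatches(s, regexpr("-?\\d+(\\.\\d+)?", s))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

.extraction_tasks <- c("characteristics", "arm_design", "participant_stats",
                       "trial_results")

#' Structured data extraction through a backend
#'
#' Runs one of the four extraction tasks — study characteristics, arm
#' design, participant statistics, trial results — on a study: renders the
#' task prompt with the request and the truncated document, asks the
#' backend, parses the fenced-JSON answer against the task schema, and
#' validates invariants (unique arm labels; result `group_id`s must exist
#' among request groups; numeric fields parse after unit/percent/separator
#' stripping). Missing optional fields yield per-field `NA` markers;
#' values are never coerced across kinds. The oracle backend reproduces
#' the study's registry truth exactly.
#'
#' @param task One of `"characteristics"`, `"arm_design"`,
#'   `"participant_stats"`, `"trial_results"`.
#' @param request Task request: a schema from [characteristics_schema()],
#'   `NULL` (arm design needs none), a [participant_stats_request()], or a
#'   [trial_result_request()].
#' @param study A [study_record()] with content.
#' @param backend A generative backend.
#' @param budget_tokens Document truncation budget.
#' @param seed Optional seed forwarded to the backend.
#' @return A task-typed result: for `characteristics` a named list of
#'   field values; for `arm_design` a list of [arm_record()]s; for the two
#'   numeric tasks a tibble of results.
#' @export
extract_structured <- function(task, request, study, backend,
                               budget_tokens = 30000, seed = NULL) {
  task <- match.arg(task, .extraction_tasks)
  stopifnot(inherits(study, "study_record"))
  req_json <- switch(task,
    characteristics = jsonlite::toJSON(
      lapply(unclass(request %||% characteristics_schema()), function(f) {
        list(name = f$name, value_kind = f$value_kind, description = f$description)
      }),
      auto_unbox = TRUE
    ),
    arm_design = jsonlite::toJSON(list(fields = c("label", "arm_type", "description",
                                                  "intervention_names")),
                                  auto_unbox = TRUE),
    participant_stats = jsonlite::toJSON(unclass(request), auto_unbox = TRUE, digits = NA),
    trial_results = jsonlite::toJSON(unclass(request), auto_unbox = TRUE, digits = NA)
  )
  prompt <- render_prompt(task, list(
    study_id = study$study_id,
    request = as.character(req_json),
    document = truncate_document(study, budget_tokens)
  ))
  raw <- backend_complete(backend, prompt, seed = seed)
  parsed <- parse_backend_json(raw, sprintf("%s extraction for study '%s'", task, study$study_id))
  switch(task,
    characteristics = .validate_characteristics(parsed, request %||% characteristics_schema()),
    arm_design = .validate_arms(parsed),
    participant_stats = .validate_participant_stats(parsed, request),
    trial_results = .validate_trial_results(parsed)
  )
}

.validate_characteristics <- function(parsed, schema) {
  out <- list()
  for (f in schema) {
    v <- parsed[[f$name]]
    if (is.null(v)) {
      out[[f$name]] <- NA # absent marker
      next
    }
    if (f$value_kind == "number") {
      num <- parse_numeric_field(if (is.list(v)) v[[1]] else v)
      if (is.na(num)) {
        stop_litmine(sprintf("characteristics: field '%s' is not numeric", f$name),
                     "validation", fields = f$name)
      }
      out[[f$name]] <- num
    } else {
      out[[f$name]] <- unlist(v, use.names = FALSE)
    }
  }
  structure(out, class = "characteristics_result")
}

.validate_arms <- function(parsed) {
  arms <- parsed$arms %||% parsed
  if (!length(arms)) stop_litmine("arm_design: no arms in output", "validation")
  labels <- vapply(arms, function(a) as.character(a$label %||% ""), character(1))
  if (any(!nzchar(labels))) {
    stop_litmine("arm_design: arm with missing label", "validation", fields = "label")
  }
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop_litmine(sprintf("arm_design: duplicate arm label '%s'", dup[1]),
                 "validation", fields = "label")
  }
  lapply(arms, function(a) {
    arm_record(
      label = a$label, arm_type = as.character(a$arm_type %||% NA),
      description = as.character(a$description %||% NA),
      intervention_names = unlist(a$intervention_names, use.names = FALSE) %||% character()
    )
  })
}

.validate_participant_stats <- function(parsed, request) {
  stopifnot(inherits(request, "participant_stats_request"))
  results <- parsed$results %||% parsed
  if (!length(results)) stop_litmine("participant_stats: no results in output", "validation")
  known <- vapply(request$groups, function(g) g$group_id, character(1))
  rows <- lapply(results, function(r) {
    gid <- as.character(r$group_id %||% "")
    if (!gid %in% known) {
      stop_litmine(sprintf("participant_stats: unknown group_id '%s'", gid),
                   "validation", fields = "group_id")
    }
    val <- parse_numeric_field(r$value)
    tibble(group_id = gid, value = val, notes = as.character(r$notes %||% NA))
  })
  dplyr::bind_rows(rows)
}

.validate_trial_results <- function(parsed) {
  results <- parsed$results %||% parsed
  if (!length(results)) stop_litmine("trial_results: no results in output", "validation")
  rows <- lapply(results, function(r) {
    tibble(value = parse_numeric_field(r$value),
           title = as.character(r$title %||% NA))
  })
  dplyr::bind_rows(rows)
}
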