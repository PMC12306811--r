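# Authored instruction texts per task (the user-facing half of each
# instruction triple); versioned alongside the prompt registry.
.instruction_texts <- c(
  search_query = "Generate a boolean search query, in PubMed syntax, that retrieves the studies relevant to the systematic review question below.",
  eligibility = "Assess the candidate study against each eligibility criterion, answering YES, PARTIAL, UNCERTAIN, or NO with a rationale per criterion, and report the final eligibility score.",
  characteristics = "Extract the requested study characteristics from the clinical-trial publication.",
  arm_design = "Extract the trial's arm designs (label, type, description, interventions) from the publication.",
  participant_stats = "Extract the requested participant statistics for each defined participant group from the publication.",
  trial_results = "Extract the requested trial outcome results from the publication."
)

.instruction_row <- function(task, instruction, input, output,
                             review_id = NA_character_, study_id = NA_character_) {
  stopifnot(nzchar(instruction), nzchar(input), nzchar(output))
  tibble(
    task = task, instruction = instruction, input = input, output = output,
    review_id = review_id, study_id = study_id, split = NA_character_
  )
}

.pico_text <- function(pico) {
  sprintf("Population: %s\nIntervention: %s\nComparator: %s\nOutcome: %s",
          pico$population, pico$intervention, pico$comparator, pico$outcome)
}

#' Build search-query instruction records
#'
#' For each review: extract per-study term sets from the included studies,
#' assemble the aggregated query, and keep it only if its recall on the
#' review's truth set reaches the quality threshold on the offline engine
#' (the surviving queries are the synthetic ground-truth queries). The
#' record's input is the review's PICO frame, its output the serialized
#' query. Reviews whose query is filtered out are skipped with a message.
#'
#' @param corpus A [linked_corpus()].
#' @param backend A generative backend used for term extraction.
#' @param threshold Recall threshold (default 0.2).
#' @return Tibble of instruction records.
#' @export
build_search_instructions <- function(corpus, backend, threshold = 0.2) {
  if (!length(corpus$reviews)) stop_litmine("corpus has no reviews", "config")
  rows <- list()
  for (review in corpus$reviews) {
    truth <- corpus_truth(corpus, review$review_id)
    if (!length(truth)) next
    termsets <- lapply(truth, function(sid) {
      extract_terms(corpus_study(corpus, sid), backend)
    })
    query <- assemble_query(termsets)
    verdict <- filter_by_recall(query, corpus, truth, threshold = threshold)
    if (!verdict$keep) {
      inform(sprintf("review '%s' skipped: query recall %.3f below %.2f",
                     review$review_id, verdict$recall, threshold))
      next
    }
    rows[[length(rows) + 1L]] <- .instruction_row(
      task = "search_query",
      instruction = .instruction_texts[["search_query"]],
      input = .pico_text(review$pico),
      output = serialize_pubmed(query),
      review_id = review$review_id
    )
  }
  dplyr::bind_rows(rows)
}

.analysis_output <- function(result) {
  as.character(jsonlite::toJSON(
    list(
      assessments = lapply(seq_len(nrow(result$assessments)), function(i) {
        list(label = result$assessments$label[i],
             rationale = result$assessments$rationale[i])
      }),
      final_score = result$final_score
    ),
    auto_unbox = TRUE, digits = NA
  ))
}

#' Build eligibility instruction records
#'
#' Per review: a candidate pool is built from the aggregated query's
#' retrievals; every ground-truth included study is paired with a
#' backend-generated criterion analysis, and an equal number of
#' non-included candidates (uniformly sampled with `seed`) provides the
#' negatives — a balanced 1:1 dataset per review. Any record whose study
#' is ground-truth-included but whose generated analysis aggregates to a
#' negative final score is dropped (the marked-eligible-but-negative
#' filter); drop counts are reported via a message.
#'
#' @param corpus A [linked_corpus()].
#' @param backend A generative backend producing criterion analyses.
#' @param pool_size Candidate-pool cap (default 2000).
#' @param seed Seed for negative sampling.
#' @return Tibble of instruction records.
#' @export
build_eligibility_instructions <- function(corpus, backend, pool_size = 2000,
                                           seed = 1) {
  rows <- list()
  n_dropped <- 0L
  for (review in corpus$reviews) {
    criteria <- review_criteria(review)
    if (!length(criteria)) {
      stop_litmine(sprintf("review '%s' has no criteria", review$review_id), "config")
    }
    truth <- corpus_truth(corpus, review$review_id)
    if (!length(truth)) next
    termsets <- lapply(truth, function(sid) {
      extract_terms(corpus_study(corpus, sid), backend)
    })
    primary <- retrieve(assemble_query(termsets), corpus, limit = pool_size)
    pool <- build_candidate_pool(review, corpus, primary, pool_size = pool_size)
    make_record <- function(sid) {
      res <- assess_study(criteria, corpus_study(corpus, sid), backend,
                          review_id = review$review_id)
      list(result = res, row = .instruction_row(
        task = "eligibility",
        instruction = .instruction_texts[["eligibility"]],
        input = paste0(
          "Criteria:\n",
          paste(vapply(criteria, function(cr) sprintf("- [%s/%s] %s", cr$element,
                                                      cr$role, cr$text),
                       character(1)), collapse = "\n"),
          "\n\nStudy:\n",
          truncate_document(corpus_study(corpus, sid), budget_tokens = 2000)
        ),
        output = .analysis_output(res),
        review_id = review$review_id, study_id = sid
      ))
    }
    kept_pos <- list()
    for (sid in truth) {
      rec <- make_record(sid)
      if (rec$result$final_score < 0) {
        n_dropped <- n_dropped + 1L # eligible-but-negative filter
        next
      }
      kept_pos[[length(kept_pos) + 1L]] <- rec$row
    }
    negatives_pool <- setdiff(pool, truth)
    n_neg <- min(length(kept_pos), length(negatives_pool))
    neg_ids <- withr::with_seed(
      derive_seed(seed, review$review_id),
      sample(negatives_pool, n_neg)
    )
    neg_rows <- lapply(neg_ids, function(sid) make_record(sid)$row)
    rows <- c(rows, kept_pos, neg_rows)
  }
  if (n_dropped > 0L) {
    inform(sprintf("eligibility builder: dropped %d included-study record(s) with negative score",
                   n_dropped))
  }
  dplyr::bind_rows(rows)
}

# tasks with content for a study's registry truth
.truth_tasks <- function(truth) {
  tasks <- character()
  if (length(truth$conditions) || length(truth$interventions)) {
    tasks <- c(tasks, "characteristics")
  }
  if (length(truth$arms)) tasks <- c(tasks, "arm_design")
  if (length(truth$participant_measures)) tasks <- c(tasks, "participant_stats")
  if (length(truth$outcome_results)) tasks <- c(tasks, "trial_results")
  tasks
}

.truth_output <- function(truth, task) {
  out <- switch(task,
    characteristics = list(
      conditions = as.list(truth$conditions),
      interventions = as.list(truth$interventions),
      enrollment = truth$enrollment, study_type = truth$study_type
    ),
    arm_design = list(arms = lapply(truth$arms, function(a) {
      list(label = a$label, arm_type = a$arm_type, description = a$description,
           intervention_names = as.list(a$intervention_names))
    })),
    participant_stats = list(results = truth$participant_measures[[1]]$results),
    trial_results = list(results = truth$outcome_results[[1]]$results)
  )
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
}

.truth_request_text <- function(truth, task) {
  switch(task,
    characteristics = "Fields: conditions; interventions; enrollment; study_type",
    arm_design = "Fields per arm: label; arm_type; description; intervention_names",
    participant_stats = {
      req <- truth$participant_measures[[1]]$request
      sprintf("Measure: %s (%s, %s); groups: %s",
              req$measure_definition, req$parameter_type, req$unit,
              paste(vapply(req$groups, function(g) g$group_id, character(1)),
                    collapse = ", "))
    },
    trial_results = {
      req <- truth$outcome_results[[1]]$request
      sprintf("Outcome: %s; groups: %s; %s in %s over %s",
              req$outcome_definition, req$group_definition, req$parameter_type,
              req$unit, req$timeframe)
    }
  )
}

#' Build extraction instruction records
#'
#' One record per (linked study, extraction task) for which the study's
#' registry truth carries content. The input embeds the truncated document
#' plus the request fields; the output is the truth serialization.
#'
#' @param corpus A [linked_corpus()].
#' @param budget_tokens Document truncation budget for the input.
#' @return Tibble of instruction records.
#' @export
build_extraction_instructions <- function(corpus, budget_tokens = 2000) {
  # reverse lookup: study -> first review including it
  rev_of <- list()
  for (rid in names(corpus$inclusion_truth)) {
    for (sid in corpus$inclusion_truth[[rid]]) {
      if (is.null(rev_of[[sid]])) rev_of[[sid]] <- rid
    }
  }
  rows <- list()
  for (study in corpus$studies) {
    truth <- study$registry_truth
    if (is.null(truth)) next
    doc <- truncate_document(study, budget_tokens = budget_tokens)
    for (task in .truth_tasks(truth)) {
      rows[[length(rows) + 1L]] <- .instruction_row(
        task = task,
        instruction = .instruction_texts[[task]],
        input = paste0(.truth_request_text(truth, task), "\n\nDocument:\n", doc),
        output = .truth_output(truth, task),
        review_id = rev_of[[study$study_id]] %||% NA_character_,
        study_id = study$study_id
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Assign train/dev/test splits at the review level
#'
#' Shuffles the distinct review ids with `seed` and allocates them to
#' splits in the given ratios (counts within one review of exact
#' proportions); all records of one review share its split, so no review
#' leaks across splits. Records without a `review_id` are grouped by
#' `study_id` instead.
#'
#' @param records Instruction-record tibble.
#' @param ratios Train/dev/test proportions summing to 1 (default 6:2:2).
#' @param seed Shuffle seed.
#' @return The records with `split` filled in.
#' @export
split_dataset <- function(records, ratios = c(0.6, 0.2, 0.2), seed = 1) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8) {
    stop_litmine("split_dataset: ratios must be three numbers summing to 1", "config")
  }
  key <- ifelse(is.na(records$review_id), paste0("study:", records$study_id),
                records$review_id)
  units <- sort(unique(key))
  if (length(units) < 3L) {
    stop_litmine("split_dataset: fewer grouping units (reviews) than splits", "config")
  }
  shuffled <- withr::with_seed(seed, sample(units))
  n <- length(units)
  n_train <- round(ratios[1] * n)
  n_dev <- round(ratios[2] * n)
  n_dev <- min(n_dev, n - n_train - 1L) # keep test non-empty
  assignment <- stats::setNames(
    rep(c("train", "dev", "test"),
        times = c(n_train, n_dev, n - n_train - n_dev)),
    shuffled
  )
  records$split <- unname(assignment[key])
  records
}

#' JSONL export/import of instruction records
#'
#' One JSON object per line with keys `task`, `instruction`, `input`,
#' `output`, `meta` (`review_id`, `study_id`, `split`), UTF-8, no header.
#' `import_jsonl(export_jsonl(x))` reproduces `x` exactly.
#'
#' @param records Instruction-record tibble.
#' @param path Output file path.
#' @return `export_jsonl()` returns `path` invisibly; `import_jsonl()`
#'   returns the records tibble.
#' @export
export_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    meta <- list(split = records$split[i])
    if (!is.na(records$review_id[i])) meta$review_id <- records$review_id[i]
    if (!is.na(records$study_id[i])) meta$study_id <- records$study_id[i]
    as.character(jsonlite::toJSON(
      list(task = records$task[i], instruction = records$instruction[i],
           input = records$input[i], output = records$output[i], meta = meta),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    ))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname export_jsonl
#' @export
import_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    tibble(
      task = obj$task, instruction = obj$instruction, input = obj$input,
      output = obj$output,
      review_id = obj$meta$review_id %||% NA_character_,
      study_id = obj$meta$study_id %||% NA_character_,
      split = if (is.null(obj$meta$split) || is.na(obj$meta$split)) NA_character_ else obj$meta$split
    )
  })
  dplyr::bind_rows(rows)
}

#' Build the full six-task instruction dataset
#'
#' Runs the three builders, assigns review-level splits, and attaches a
#' per-task count summary (attribute `"stats"`); asserts that the
#' combined record count equals the sum of per-task counts.
#'
#' @param corpus A [linked_corpus()].
#' @param backend A generative backend.
#' @param pool_size Eligibility candidate-pool cap.
#' @param seed Dataset seed (splits and negative sampling).
#' @return Instruction-record tibble with splits assigned.
#' @export
build_instruction_dataset <- function(corpus, backend, pool_size = 2000, seed = 1) {
  parts <- list(
    build_search_instructions(corpus, backend),
    build_eligibility_instructions(corpus, backend, pool_size = pool_size, seed = seed),
    build_extraction_instructions(corpus)
  )
  combined <- dplyr::bind_rows(parts)
  stopifnot(nrow(combined) == sum(vapply(parts, nrow, integer(1)))) # conservation
  combined <- split_dataset(combined, seed = seed)
  stats <- combined |>
    dplyr::count(.data$task, .data$split, name = "n_records")
  attr(combined, "stats") <- stats
  combined
}
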