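# Versioned prompt-template registry. Templates are original compositions
# covering the task description, the structured inputs (PICO, criteria,
# field definitions) and the output-format contract. Each template embeds a
# machine-readable context block ("[[key: value]]" lines) so corpus-bound
# test backends can resolve the referenced review/study, and instruction
# datasets record the template version they were built with.

.litmine_prompts <- new.env(parent = emptyenv())

#' Register or fetch prompt templates
#'
#' Templates use `{name}` placeholders; rendering fails loudly on any
#' placeholder without a matching variable.
#'
#' @param task Task key, e.g. `"eligibility"`.
#' @param template Template text with `{name}` placeholders.
#' @param version Version tag recorded alongside the template.
#' @return `prompt_template()` returns the registered template object;
#'   `get_prompt_template()` fetches one by task key.
#' @export
prompt_template <- function(task, template, version = "1") {
  if (!is_nonempty_string(task)) stop_litmine("prompt_template: task key required", "config")
  if (!is_nonempty_string(template)) stop_litmine("prompt_template: template required", "config")
  obj <- structure(list(task = task, template = template, version = version),
                   class = "prompt_template")
  assign(task, obj, envir = .litmine_prompts)
  obj
}

#' @rdname prompt_template
#' @export
get_prompt_template <- function(task) {
  if (!exists(task, envir = .litmine_prompts, inherits = FALSE)) {
    stop_litmine(sprintf("no prompt template registered for task '%s'", task), "lookup")
  }
  get(task, envir = .litmine_prompts, inherits = FALSE)
}

#' Render a prompt template
#'
#' Pure substitution of `{name}` placeholders from `variables`; no silent
#' defaults — a placeholder without a variable raises a render error
#' naming it.
#'
#' @param template A `prompt_template` (or task key string).
#' @param variables Named list/character of placeholder values.
#' @return Rendered prompt text.
#' @export
render_prompt <- function(template, variables = list()) {
  if (is.character(template)) template <- get_prompt_template(template)
  stopifnot(inherits(template, "prompt_template"))
  text <- template$template
  holes <- unique(regmatches(text, gregexpr("\\{[a-z_]+\\}", text))[[1]])
  for (h in holes) {
    key <- substr(h, 2, nchar(h) - 1L)
    if (is.null(variables[[key]])) {
      stop_litmine(sprintf("render_prompt: missing placeholder '%s'", key),
                   "render_error", placeholder = key)
    }
    text <- gsub(h, variables[[key]], text, fixed = TRUE)
  }
  text
}

# parse the [[key: value]] context block out of a rendered prompt
prompt_context <- function(prompt) {
  m <- regmatches(prompt, gregexpr("\\[\\[([a-z_]+): ([^]]*)\\]\\]", prompt))[[1]]
  out <- list()
  for (line in m) {
    parts <- regmatches(line, regexec("\\[\\[([a-z_]+): ([^]]*)\\]\\]", line))[[1]]
    out[[parts[2]]] <- parts[3]
  }
  out
}

.register_default_prompts <- function() {
  prompt_template("term_extraction", paste(
    "[[task: term_extraction]]",
    "[[study_id: {study_id}]]",
    "You are building a boolean literature-search strategy for a systematic review.",
    "Read the study below and extract up to ten population keywords and up to ten",
    "intervention keywords that a search query should use to find this study.",
    "Study title: {title}",
    "Study abstract: {abstract}",
    "Answer with a fenced JSON object:",
    '```json',
    '{"population": ["..."], "intervention": ["..."]}',
    '```',
    sep = "\n"
  ), version = "1")

  prompt_template("search_query", paste(
    "[[task: search_query]]",
    "[[review_id: {review_id}]]",
    "Generate keyword groups for a boolean literature-search query answering the",
    "research question framed by the PICO elements below. Population keywords are",
    "combined with AND, as are intervention keywords; the two groups are joined",
    "with AND.",
    "Population: {population}",
    "Intervention: {intervention}",
    "Comparator: {comparator}",
    "Outcome: {outcome}",
    "Answer with a fenced JSON object:",
    '```json',
    '{"population": ["..."], "intervention": ["..."]}',
    '```',
    sep = "\n"
  ), version = "1")

  prompt_template("eligibility", paste(
    "[[task: eligibility]]",
    "[[review_id: {review_id}]]",
    "[[study_id: {study_id}]]",
    "Assess the study below against each eligibility criterion of a systematic",
    "review. For every criterion answer one of YES, PARTIAL, UNCERTAIN, NO",
    "(for exclusion criteria, YES means the study satisfies the requirement once",
    "the exclusion is negated) and give a one-sentence rationale.",
    "Criteria (JSON): {criteria}",
    "Study title: {title}",
    "Study abstract: {abstract}",
    "Answer with a fenced JSON array, one object per criterion, in order:",
    '```json',
    '[{"label": "YES", "rationale": "..."}]',
    '```',
    sep = "\n"
  ), version = "1")

  for (task in c("characteristics", "arm_design", "participant_stats", "trial_results")) {
    prompt_template(task, paste(
      sprintf("[[task: %s]]", task),
      "[[study_id: {study_id}]]",
      "Extract the requested structured fields from the clinical-trial publication",
      "below. Report values exactly as stated in the document; do not guess.",
      "Request (JSON): {request}",
      "Document:",
      "{document}",
      "Answer with a single fenced JSON object matching the requested schema.",
      sep = "\n"
    ), version = "1")
  }
  invisible(NULL)
}
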