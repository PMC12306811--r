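#' Generative backend contract
#'
#' A generative backend answers a rendered prompt with text. Every
#' pipeline stage talks to backends only through [backend_complete()], so
#' a trained model, an HTTP API, and the corpus-bound test oracles are
#' interchangeable. Deterministic backends return identical text for
#' identical `(prompt, seed)`.
#'
#' @param backend A backend object.
#' @param prompt Rendered prompt text.
#' @param seed Optional integer seed forwarded to stochastic backends.
#' @param ... Backend-specific options.
#' @return A single string (the completion).
#' @export
backend_complete <- function(backend, prompt, seed = NULL, ...) {
  UseMethod("backend_complete")
}

#' @rdname backend_complete
#' @export
is_deterministic <- function(backend) {
  isTRUE(attr(backend, "deterministic"))
}

#' Corpus-bound oracle backend
#'
#' A deterministic test double standing in for a trained model: it
#' resolves the task and the review/study identifiers from the prompt's
#' context block and answers from the corpus's planted ground truth —
#' exact planted term sets for query tasks, all-YES criterion analyses for
#' ground-truth-included studies and all-NO analyses for distractors, and
#' verbatim registry-truth serialisations for the extraction tasks. Every
#' pipeline stage is therefore verifiable offline.
#'
#' @param corpus The [linked_corpus()] the oracle answers from.
#' @return An `oracle_backend`.
#' @export
oracle_backend <- function(corpus) {
  stopifnot(inherits(corpus, "linked_corpus"))
  structure(list(corpus = corpus), class = c("oracle_backend", "litmine_backend"),
            deterministic = TRUE)
}

#' @export
backend_complete.oracle_backend <- function(backend, prompt, seed = NULL, ...) {
  ctx <- prompt_context(prompt)
  task <- ctx$task %||% stop_litmine("oracle: prompt carries no task tag", "oracle")
  switch(task,
    term_extraction = .oracle_terms_study(backend$corpus, ctx),
    search_query = .oracle_terms_review(backend$corpus, ctx),
    eligibility = .oracle_eligibility(backend$corpus, ctx),
    characteristics = ,
    arm_design = ,
    participant_stats = ,
    trial_results = .oracle_extraction(backend$corpus, ctx, task, prompt),
    stop_litmine(sprintf("oracle: unknown task '%s'", task), "oracle")
  )
}

.fenced_json <- function(x) {
  paste0("```json\n", jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), "\n```")
}

.oracle_terms_study <- function(corpus, ctx) {
  sid <- ctx$study_id %||% stop_litmine("oracle: no study_id in prompt", "oracle")
  study <- corpus_study(corpus, sid)
  pt <- study$planted_terms
  if (is.null(pt)) {
    # non-synthetic study: fall back to leading content words
    toks <- tokenize(paste(study$title, study$abstract))
    pt <- list(population = utils::head(unique(toks), 3),
               intervention = utils::head(rev(unique(toks)), 3))
  }
  .fenced_json(list(population = as.list(pt$population),
                    intervention = as.list(pt$intervention)))
}

.oracle_terms_review <- function(corpus, ctx) {
  rid <- ctx$review_id %||% stop_litmine("oracle: no review_id in prompt", "oracle")
  review <- corpus_review(corpus, rid)
  pop <- trimws(strsplit(review$pico$population, ";")[[1]])
  int <- trimws(strsplit(review$pico$intervention, ";")[[1]])
  .fenced_json(list(population = as.list(compact_chr(pop)),
                    intervention = as.list(compact_chr(int))))
}

.oracle_eligibility <- function(corpus, ctx) {
  rid <- ctx$review_id %||% stop_litmine("oracle: no review_id in prompt", "oracle")
  sid <- ctx$study_id %||% stop_litmine("oracle: no study_id in prompt", "oracle")
  review <- corpus_review(corpus, rid)
  corpus_study(corpus, sid) # existence check
  included <- sid %in% corpus_truth(corpus, rid)
  crits <- review_criteria(review)
  answers <- lapply(crits, function(cr) {
    if (included) {
      list(label = "YES",
           rationale = sprintf("study meets the %s criterion", cr$element))
    } else {
      list(label = "NO",
           rationale = sprintf("study does not meet the %s criterion", cr$element))
    }
  })
  .fenced_json(answers)
}

.oracle_extraction <- function(corpus, ctx, task, prompt) {
  sid <- ctx$study_id %||% stop_litmine("oracle: no study_id in prompt", "oracle")
  study <- corpus_study(corpus, sid)
  truth <- study$registry_truth
  if (is.null(truth)) {
    stop_litmine(sprintf("oracle: study '%s' has no registry_truth", sid), "oracle")
  }
  out <- switch(task,
    characteristics = list(
      conditions = as.list(truth$conditions),
      interventions = as.list(truth$interventions),
      enrollment = truth$enrollment,
      study_type = truth$study_type
    ),
    arm_design = list(
      arms = lapply(truth$arms, function(a) {
        list(label = a$label, arm_type = a$arm_type, description = a$description,
             intervention_names = as.list(a$intervention_names))
      })
    ),
    participant_stats = {
      entry <- .match_truth_entry(truth$participant_measures, prompt,
                                  "measure_definition")
      list(results = entry$results)
    },
    trial_results = {
      entry <- .match_truth_entry(truth$outcome_results, prompt,
                                  "outcome_definition")
      list(results = entry$results)
    }
  )
  .fenced_json(out)
}

# pick the truth entry whose request definition appears in the prompt body;
# falls back to the first entry
.match_truth_entry <- function(entries, prompt, def_field) {
  if (!length(entries)) stop_litmine("oracle: no truth entries for task", "oracle")
  for (e in entries) {
    if (grepl(e$request[[def_field]], prompt, fixed = TRUE)) return(e)
  }
  entries[[1L]]
}

#' Noisy oracle backend
#'
#' Wraps [oracle_backend()] with seeded, per-item corruption at rate
#' `error_rate`: eligibility YES labels flip to NO independently per
#' criterion, and query-task terms are replaced by junk terms absent from
#' the corpus. `error_rate = 0` reduces exactly to the oracle. Corruption
#' is a pure function of `(prompt, backend seed, call seed)`, so runs are
#' reproducible while different studies and replicates decorrelate.
#'
#' @inheritParams oracle_backend
#' @param error_rate Corruption probability in `[0, 1]`.
#' @param seed Backend-level integer seed.
#' @return A `noisy_oracle_backend`.
#' @export
noisy_oracle_backend <- function(corpus, error_rate = 0.1, seed = 1) {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1) {
    stop_litmine("noisy_oracle_backend: error_rate must lie in [0, 1]", "config")
  }
  structure(
    list(corpus = corpus, error_rate = error_rate, seed = as.integer(seed)),
    class = c("noisy_oracle_backend", "litmine_backend"),
    deterministic = TRUE
  )
}

#' @export
backend_complete.noisy_oracle_backend <- function(backend, prompt, seed = NULL, ...) {
  clean <- backend_complete.oracle_backend(backend, prompt, seed = seed, ...)
  eps <- backend$error_rate
  if (eps == 0) return(clean)
  ctx <- prompt_context(prompt)
  rng_seed <- derive_seed(backend$seed, seed %||% 0L, text_hash(prompt))
  withr::with_seed(rng_seed, {
    if (identical(ctx$task, "eligibility")) {
      answers <- parse_backend_json(clean, "noisy oracle eligibility")
      answers <- lapply(answers, function(a) {
        if (identical(a$label, "YES") && stats::runif(1) < eps) {
          a$label <- "NO"
          a$rationale <- "noisy flip"
        }
        a
      })
      .fenced_json(answers)
    } else if (ctx$task %in% c("term_extraction", "search_query")) {
      groups <- parse_backend_json(clean, "noisy oracle terms")
      groups <- lapply(groups, function(terms) {
        lapply(terms, function(t) {
          if (stats::runif(1) < eps) {
            sprintf("xq%07d", sample.int(9999999L, 1))
          } else t
        })
      })
      .fenced_json(groups)
    } else {
      clean
    }
  })
}

#' Mock backend with canned responses
#'
#' For tests of parsing and error paths: answers from a fixed character
#' vector (cycled) or a `function(prompt, seed)`.
#'
#' @param responses Character vector or function.
#' @return A `mock_backend`.
#' @export
mock_backend <- function(responses) {
  if (!is.function(responses)) {
    responses <- as.character(responses)
    stopifnot(length(responses) >= 1L)
  }
  st <- new.env(parent = emptyenv())
  st$i <- 0L
  structure(list(responses = responses, state = st),
            class = c("mock_backend", "litmine_backend"), deterministic = TRUE)
}

#' @export
backend_complete.mock_backend <- function(backend, prompt, seed = NULL, ...) {
  if (is.function(backend$responses)) return(backend$responses(prompt, seed))
  st <- backend$state
  st$i <- st$i + 1L
  backend$responses[[(st$i - 1L) %% length(backend$responses) + 1L]]
}

#' OpenAI-compatible chat API backend (network adapter)
#'
#' A thin adapter posting the prompt to an OpenAI-compatible
#' `/chat/completions` endpoint via the system `curl` binary, with bounded
#' retry. Credentials come from an environment variable, never from
#' arguments or config files. This adapter is a runtime convenience; it
#' is excluded from the test suite, which runs entirely offline against
#' the oracle backends.
#'
#' @param endpoint Base URL, e.g. `"https://api.example.com/v1"`.
#' @param model Model name sent in the request.
#' @param api_key_env Name of the environment variable holding the key.
#' @param temperature Sampling temperature.
#' @param max_retries Bounded retry count on transport failure.
#' @return An `api_backend`.
#' @export
api_backend <- function(endpoint, model, api_key_env = "LITMINE_API_KEY",
                        temperature = 0.7, max_retries = 3) {
  structure(
    list(endpoint = endpoint, model = model, api_key_env = api_key_env,
         temperature = temperature, max_retries = max_retries),
    class = c("api_backend", "litmine_backend"), deterministic = FALSE
  )
}

#' @export
backend_complete.api_backend <- function(backend, prompt, seed = NULL, ...) {
  key <- Sys.getenv(backend$api_key_env, unset = "")
  if (!nzchar(key)) {
    stop_litmine(sprintf("api_backend: environment variable '%s' not set",
                         backend$api_key_env), "config")
  }
  body <- jsonlite::toJSON(list(
    model = backend$model,
    temperature = backend$temperature,
    seed = seed,
    messages = list(list(role = "user", content = prompt))
  ), auto_unbox = TRUE)
  url <- paste0(sub("/$", "", backend$endpoint), "/chat/completions")
  for (attempt in seq_len(backend$max_retries)) {
    out <- tryCatch(
      system2("curl",
              c("-sS", "--fail", "-X", "POST", url,
                "-H", "Content-Type: application/json",
                "-H", paste0("Authorization: Bearer ", key),
                "-d", shQuote(body)),
              stdout = TRUE, stderr = FALSE),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(out) && length(out)) {
      parsed <- tryCatch(jsonlite::fromJSON(paste(out, collapse = ""),
                                            simplifyVector = FALSE),
                         error = function(e) NULL)
      content <- parsed$choices[[1]]$message$content
      if (!is.null(content)) return(content)
    }
    Sys.sleep(min(2^attempt, 8)) # bounded backoff
  }
  stop_litmine("api_backend: request failed after retries", "backend")
}

#' Backend configuration from a YAML/JSON file
#'
#' Reads `{kind: oracle|noisy_oracle|api, ...}` and constructs the
#' backend. Oracle kinds need `corpus` supplied by the caller.
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @param corpus Corpus for oracle kinds.
#' @return A backend object.
#' @export
backend_from_config <- function(path, corpus = NULL) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_litmine("yaml package required for YAML configs", "config")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  kind <- cfg$kind %||% stop_litmine("backend config: 'kind' missing", "config")
  switch(kind,
    oracle = oracle_backend(corpus),
    noisy_oracle = noisy_oracle_backend(corpus, error_rate = cfg$error_rate %||% 0.1,
                                        seed = cfg$seed %||% 1),
    api = api_backend(cfg$endpoint, cfg$model,
                      api_key_env = cfg$api_key_env %||% "LITMINE_API_KEY",
                      temperature = cfg$temperature %||% 0.7),
    stop_litmine(sprintf("backend config: unknown kind '%s'", kind), "config")
  )
}
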