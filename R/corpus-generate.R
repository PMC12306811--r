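# Fixed real-word seed vocabulary: conditions and interventions a screening
# corpus would plausibly mention. Multiword entries exercise phrase matching.
.litmine_conditions <- c(
  "atrial fibrillation", "type 2 diabetes", "heart failure", "major depression",
  "chronic kidney disease", "rheumatoid arthritis", "asthma", "hypertension",
  "multiple sclerosis", "breast cancer", "stroke", "osteoporosis",
  "chronic obstructive pulmonary disease", "epilepsy", "psoriasis",
  "ulcerative colitis", "migraine", "sepsis", "obesity", "glaucoma"
)

.litmine_interventions <- c(
  "warfarin", "metformin", "lisinopril", "sertraline", "atorvastatin",
  "methotrexate", "salbutamol", "amlodipine", "interferon beta", "tamoxifen",
  "alteplase", "alendronate", "tiotropium", "levetiracetam", "adalimumab",
  "mesalazine", "sumatriptan", "ceftriaxone", "semaglutide", "latanoprost"
)

# Pronounceable pseudo-terms: deterministic CV-syllable words indexed by i.
pseudo_term <- function(i) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  i <- i - 1L
  syl <- character(3)
  for (s in 1:3) {
    c_i <- i %% length(cons); i <- i %/% length(cons)
    v_i <- i %% length(vow); i <- i %/% length(vow)
    syl[s] <- paste0(cons[c_i + 1L], vow[v_i + 1L])
  }
  paste0(syl, collapse = "")
}

#' Configuration for the synthetic linked-corpus generator
#'
#' @param n_reviews Number of review topics.
#' @param included_per_review Ground-truth included studies per review (the
#'   truth-set size N).
#' @param distractors_per_review Non-included candidate studies per review.
#' @param vocab_size Size of the pseudo-term vocabulary used for planted
#'   terms and filler text.
#' @param overlap_rate Probability, per review-level planted term, that a
#'   distractor also contains that term (Binomial thinning of the review's
#'   term set). `0` means distractors share no planted term.
#' @param seed Integer seed; identical configs (including seed) reproduce
#'   byte-identical corpora.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_reviews = 10, included_per_review = 10,
                             distractors_per_review = 90, vocab_size = 400,
                             overlap_rate = 0.3, seed = 1) {
  for (f in c("n_reviews", "included_per_review", "distractors_per_review", "vocab_size")) {
    v <- get(f)
    if (!is_count(v)) {
      stop_litmine(sprintf("synthetic_config: '%s' must be a positive integer", f),
                   "config", field = f)
    }
  }
  if (!is.numeric(overlap_rate) || length(overlap_rate) != 1L || is.na(overlap_rate) ||
      overlap_rate < 0 || overlap_rate > 1) {
    stop_litmine("synthetic_config: 'overlap_rate' must lie in [0, 1]",
                 "config", field = "overlap_rate")
  }
  if (!is_count(seed + 1)) {
    stop_litmine("synthetic_config: 'seed' must be an integer", "config", field = "seed")
  }
  needed <- n_reviews * (6 + 2 * included_per_review)
  if (vocab_size < needed + 50) {
    stop_litmine(
      sprintf("synthetic_config: 'vocab_size' too small (%d planted terms + filler needed)",
              needed),
      "config", field = "vocab_size"
    )
  }
  structure(
    list(
      n_reviews = as.integer(n_reviews),
      included_per_review = as.integer(included_per_review),
      distractors_per_review = as.integer(distractors_per_review),
      vocab_size = as.integer(vocab_size),
      overlap_rate = overlap_rate,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# filler sentence from the non-planted slice of the vocabulary
.filler <- function(filler_vocab, n_words) {
  paste(sample(filler_vocab, n_words, replace = TRUE), collapse = " ")
}

.make_registry_truth <- function(condition, intervention, comparator_name, idx) {
  arm1 <- arm_record(
    label = sprintf("Arm A%d", idx), arm_type = "EXPERIMENTAL",
    description = sprintf("participants receiving %s", intervention),
    intervention_names = intervention
  )
  arm2 <- arm_record(
    label = sprintf("Arm B%d", idx), arm_type = "PLACEBO_COMPARATOR",
    description = sprintf("participants receiving %s", comparator_name),
    intervention_names = comparator_name
  )
  enrollment <- sample(50:500, 1)
  mean_age_1 <- round(stats::runif(1, 40, 75), 1)
  mean_age_2 <- round(stats::runif(1, 40, 75), 1)
  pm_request <- participant_stats_request(
    measure_definition = "Age of participants at baseline",
    parameter_type = "MEAN", unit = "years",
    groups = list(
      list(group_id = "G1", unit = "years", value = NA_real_,
           definition = arm1$description),
      list(group_id = "G2", unit = "years", value = NA_real_,
           definition = arm2$description)
    )
  )
  responders_1 <- sample(5:200, 1)
  responders_2 <- sample(5:200, 1)
  tr_request <- trial_result_request(
    outcome_definition = sprintf("number of participants with improvement in %s", condition),
    group_definition = "all randomised participants",
    parameter_type = "COUNT_OF_PARTICIPANTS", unit = "participants",
    timeframe = "12 weeks", denominator_unit = "participants",
    denominator_value = enrollment
  )
  registry_data(
    conditions = condition,
    interventions = c(intervention, comparator_name),
    enrollment = enrollment,
    study_type = "INTERVENTIONAL",
    arms = list(arm1, arm2),
    participant_measures = list(list(
      request = pm_request,
      results = list(
        list(group_id = "G1", value = mean_age_1, notes = "baseline"),
        list(group_id = "G2", value = mean_age_2, notes = "baseline")
      )
    )),
    outcome_results = list(list(
      request = tr_request,
      results = list(
        list(value = responders_1, title = "experimental group"),
        list(value = responders_2, title = "comparator group")
      )
    ))
  )
}

# Render registry truth verbatim into pseudo-full-text sections and table
# blocks so extraction is checkable round-trip by plain text scan.
.render_truth_text <- function(truth) {
  arms_txt <- vapply(truth$arms, function(a) {
    sprintf("%s [%s]: %s (interventions: %s)",
            a$label, a$arm_type, a$description,
            paste(a$intervention_names, collapse = ", "))
  }, character(1))
  full_text <- paste(
    sprintf("Conditions studied: %s.", paste(truth$conditions, collapse = ", ")),
    sprintf("Interventions: %s.", paste(truth$interventions, collapse = ", ")),
    sprintf("Enrollment: %d participants.", truth$enrollment),
    sprintf("Study type: %s.", truth$study_type),
    paste("Trial arms:", paste(arms_txt, collapse = "; "), "."),
    sep = "\n"
  )
  tables <- character()
  for (pm in truth$participant_measures) {
    rows <- vapply(pm$results, function(r) {
      sprintf("%s | %s | %s", r$group_id, format(r$value), r$notes)
    }, character(1))
    tables <- c(tables, paste(
      sprintf("Measure: %s (%s, %s)", pm$request$measure_definition,
              pm$request$parameter_type, pm$request$unit),
      paste(rows, collapse = "\n"), sep = "\n"
    ))
  }
  for (tr in truth$outcome_results) {
    rows <- vapply(tr$results, function(r) {
      sprintf("%s | %s", r$title, format(r$value))
    }, character(1))
    tables <- c(tables, paste(
      sprintf("Outcome: %s; groups: %s; %s in %s over %s; denominator %s %s",
              tr$request$outcome_definition, tr$request$group_definition,
              tr$request$parameter_type, tr$request$unit, tr$request$timeframe,
              format(tr$request$denominator_value), tr$request$denominator_unit),
      paste(rows, collapse = "\n"), sep = "\n"
    ))
  }
  list(full_text = full_text, table_text = tables)
}

#' Generate a synthetic linked corpus with planted ground truth
#'
#' Builds reviews with PICO frames and criteria, included studies whose
#' titles/abstracts contain the review's planted population and
#' intervention terms (plus one study-specific term of each kind),
#' distractors sharing a Binomial(`overlap_rate`)-thinned subset of the
#' review-level terms, and registry-derived structured truth embedded
#' verbatim in each included publication's pseudo full text and tables.
#' Included studies always predate their review; a fraction of distractors
#' postdate it so the time constraint is exercised.
#'
#' @param config A [synthetic_config()].
#' @return A [linked_corpus()].
#' @export
#' @examples
#' corpus <- generate_corpus(synthetic_config(n_reviews = 2, included_per_review = 3,
#'                                            distractors_per_review = 7, seed = 7))
#' corpus
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(config) {
  n_rev <- config$n_reviews
  n_inc <- config$included_per_review
  n_dis <- config$distractors_per_review

  pseudo_vocab <- vapply(seq_len(config$vocab_size), pseudo_term, character(1))
  pseudo_vocab <- unique(pseudo_vocab)
  n_planted <- n_rev * (4 + 2 * n_inc) # pseudo planted terms (2P+2I review-level + per-study)
  planted_pool <- sample(pseudo_vocab, n_planted)
  filler_vocab <- setdiff(pseudo_vocab, planted_pool)
  pool_i <- 0L
  take <- function(k) {
    out <- planted_pool[(pool_i + 1L):(pool_i + k)]
    pool_i <<- pool_i + k
    out
  }

  conditions <- sample(.litmine_conditions, n_rev, replace = n_rev > length(.litmine_conditions))
  interventions <- sample(.litmine_interventions, n_rev, replace = n_rev > length(.litmine_interventions))
  topic_areas <- c("cardiology", "oncology", "neurology", "endocrinology",
                   "respiratory", "psychiatry")

  n_studies <- n_rev * (n_inc + n_dis)
  all_pmids <- sprintf("%08d", sample.int(89999999L, n_studies) + 10000000L)
  pmid_i <- 0L
  next_pmid <- function() {
    pmid_i <<- pmid_i + 1L
    all_pmids[pmid_i]
  }

  reviews <- list()
  studies <- list()
  truth_map <- list()
  nct_counter <- sample.int(79999999L, 1) + 10000000L

  for (r in seq_len(n_rev)) {
    rev_id <- sprintf("R%03d", r)
    pop_terms <- c(conditions[r], take(2L))
    int_terms <- c(interventions[r], take(2L))
    rev_date <- as.Date("2017-06-01") + sample(0:1500, 1)
    pico <- pico_frame(
      population = paste(pop_terms, collapse = "; "),
      intervention = paste(int_terms, collapse = "; "),
      comparator = "placebo",
      outcome = sprintf("improvement in %s", conditions[r])
    )
    crits <- list(
      criterion("P", sprintf("Adults with %s", paste(pop_terms, collapse = " and "))),
      criterion("I", sprintf("Treated with %s", paste(int_terms, collapse = " or "))),
      criterion("C", "Compared against placebo or standard care"),
      criterion("O", sprintf("Reports %s", pico$outcome))
    )
    reviews[[rev_id]] <- review_topic(
      review_id = rev_id,
      title = sprintf("Systematic review of %s for %s", interventions[r], conditions[r]),
      abstract = paste(
        sprintf("We review trials of %s in patients with %s.",
                paste(int_terms, collapse = " or "), paste(pop_terms, collapse = " and ")),
        .filler(filler_vocab, 20)
      ),
      pico = pico, criteria = crits,
      topic_area = topic_areas[(r - 1L) %% length(topic_areas) + 1L],
      pub_date = rev_date
    )

    inc_ids <- character(n_inc)
    for (k in seq_len(n_inc)) {
      sid <- next_pmid()
      inc_ids[k] <- sid
      extra_p <- take(1L)
      extra_i <- take(1L)
      study_pop <- c(pop_terms, extra_p)
      study_int <- c(int_terms, extra_i)
      nct_counter <- nct_counter + 1L
      truth <- .make_registry_truth(conditions[r], interventions[r], "placebo", k)
      rendered <- .render_truth_text(truth)
      title <- sprintf("A randomised trial of %s in %s", interventions[r], conditions[r])
      abstract <- paste(
        sprintf("Background: patients with %s.", paste(study_pop, collapse = ", ")),
        sprintf("Methods: participants received %s.", paste(study_int, collapse = ", ")),
        .filler(filler_vocab, 25)
      )
      studies[[sid]] <- study_record(
        study_id = sid, kind = "publication", title = title, abstract = abstract,
        full_text = rendered$full_text, table_text = rendered$table_text,
        pub_date = rev_date - sample(30:2500, 1),
        nct_link = sprintf("NCT%08d", nct_counter %% 100000000),
        registry_truth = truth,
        planted_terms = list(population = study_pop, intervention = study_int)
      )
    }
    truth_map[[rev_id]] <- inc_ids

    review_terms <- c(pop_terms, int_terms)
    for (k in seq_len(n_dis)) {
      sid <- next_pmid()
      shared <- if (config$overlap_rate > 0) {
        review_terms[stats::runif(length(review_terms)) < config$overlap_rate]
      } else {
        character()
      }
      body <- paste(c(shared, strsplit(.filler(filler_vocab, 30), " ")[[1]]), collapse = " ")
      postdates <- stats::runif(1) < 0.1
      studies[[sid]] <- study_record(
        study_id = sid, kind = "publication",
        title = sprintf("Observational study of %s", sample(filler_vocab, 1)),
        abstract = body,
        pub_date = if (postdates) rev_date + sample(1:365, 1) else rev_date - sample(1:2500, 1)
      )
    }
  }

  linked_corpus(reviews = unname(reviews), studies = unname(studies),
                inclusion_truth = truth_map)
}
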