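.registry_to_list <- function(truth) {
  if (is.null(truth)) return(NULL)
  list(
    conditions = as.list(truth$conditions),
    interventions = as.list(truth$interventions),
    enrollment = truth$enrollment,
    study_type = truth$study_type,
    arms = lapply(truth$arms, function(a) {
      list(label = a$label, arm_type = a$arm_type, description = a$description,
           intervention_names = as.list(a$intervention_names))
    }),
    participant_measures = lapply(truth$participant_measures, function(pm) {
      list(request = unclass(pm$request), results = pm$results)
    }),
    outcome_results = lapply(truth$outcome_results, function(tr) {
      list(request = unclass(tr$request), results = tr$results)
    })
  )
}

.registry_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  registry_data(
    conditions = unlist(x$conditions, use.names = FALSE) %||% character(),
    interventions = unlist(x$interventions, use.names = FALSE) %||% character(),
    enrollment = x$enrollment %||% 0L,
    study_type = x$study_type %||% "INTERVENTIONAL",
    arms = lapply(x$arms, function(a) {
      arm_record(a$label, a$arm_type, a$description,
                 unlist(a$intervention_names, use.names = FALSE) %||% character())
    }),
    participant_measures = lapply(x$participant_measures, function(pm) {
      list(request = do.call(participant_stats_request, pm$request[
        c("measure_definition", "parameter_type", "unit", "groups")
      ]), results = pm$results)
    }),
    outcome_results = lapply(x$outcome_results, function(tr) {
      list(request = do.call(trial_result_request, tr$request[
        c("outcome_definition", "group_definition", "parameter_type", "unit",
          "timeframe", "denominator_unit", "denominator_value")
      ]), results = tr$results)
    })
  )
}

#' Corpus JSON serialization
#'
#' One JSON document per corpus (the schema ships in
#' `inst/extdata/corpus-schema.json`). `corpus_to_json()` returns the
#' document as a string, `write_corpus()`/`read_corpus()` round-trip a
#' corpus through a file: `read_corpus(write_corpus(x))` reproduces `x`.
#'
#' @param corpus A [linked_corpus()].
#' @param path File path.
#' @return `corpus_to_json()` a string; `write_corpus()` `path`
#'   invisibly; `read_corpus()` a [linked_corpus()].
#' @export
corpus_to_json <- function(corpus) {
  doc <- list(
    format = "litmine-corpus",
    version = 1L,
    reviews = lapply(corpus$reviews, function(r) {
      list(
        review_id = r$review_id, title = r$title, abstract = r$abstract,
        pico = unclass(r$pico),
        criteria = lapply(r$criteria, unclass),
        topic_area = r$topic_area, pub_date = as.character(r$pub_date)
      )
    }),
    studies = lapply(corpus$studies, function(s) {
      list(
        study_id = s$study_id, kind = s$kind, title = s$title,
        abstract = s$abstract, full_text = s$full_text,
        table_text = if (is.null(s$table_text)) NULL else as.list(s$table_text),
        pub_date = if (is.na(s$pub_date)) NULL else as.character(s$pub_date),
        nct_link = s$nct_link,
        registry_truth = .registry_to_list(s$registry_truth),
        planted_terms = if (is.null(s$planted_terms)) NULL else {
          list(population = as.list(s$planted_terms$population),
               intervention = as.list(s$planted_terms$intervention))
        }
      )
    }),
    inclusion_truth = lapply(corpus$inclusion_truth, as.list)
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' @rdname corpus_to_json
#' @export
write_corpus <- function(corpus, path) {
  writeLines(corpus_to_json(corpus), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname corpus_to_json
#' @export
read_corpus <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "litmine-corpus")) {
    stop_litmine("read_corpus: not a litmine corpus document", "parse_error")
  }
  reviews <- lapply(doc$reviews, function(r) {
    review_topic(
      review_id = r$review_id, title = r$title, abstract = r$abstract,
      pico = pico_frame(r$pico$population, r$pico$intervention,
                        r$pico$comparator %||% "", r$pico$outcome %||% ""),
      criteria = lapply(r$criteria, function(cr) criterion(cr$element, cr$text, cr$role)),
      topic_area = r$topic_area, pub_date = r$pub_date
    )
  })
  studies <- lapply(doc$studies, function(s) {
    study_record(
      study_id = s$study_id, kind = s$kind, title = s$title, abstract = s$abstract,
      full_text = s$full_text,
      table_text = if (is.null(s$table_text)) NULL else unlist(s$table_text, use.names = FALSE),
      pub_date = s$pub_date %||% NA,
      nct_link = s$nct_link,
      registry_truth = .registry_from_list(s$registry_truth),
      planted_terms = if (is.null(s$planted_terms)) NULL else {
        list(population = unlist(s$planted_terms$population, use.names = FALSE),
             intervention = unlist(s$planted_terms$intervention, use.names = FALSE))
      }
    )
  })
  linked_corpus(reviews, studies,
                lapply(doc$inclusion_truth, function(x) unlist(x, use.names = FALSE)))
}

#' Map PubMed efetch XML onto study records
#'
#' Reader adapter for `PubmedArticleSet` payloads (as returned by the
#' E-utilities efetch endpoint): PMID, title, abstract, publication date,
#' and any ClinicalTrials.gov accession in the data-bank list become a
#' publication [study_record()]. Network access is the caller's business;
#' this function only parses XML already in hand.
#'
#' @param xml Path to an XML file or a single XML string.
#' @return List of [study_record()]s.
#' @export
read_pubmed_xml <- function(xml) {
  doc <- xml2::read_xml(xml)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abstract <- paste(
      xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText")),
      collapse = " "
    )
    y <- xml2::xml_text(xml2::xml_find_first(a, ".//PubDate/Year"))
    m <- xml2::xml_text(xml2::xml_find_first(a, ".//PubDate/Month"))
    d <- xml2::xml_text(xml2::xml_find_first(a, ".//PubDate/Day"))
    pub_date <- if (is.na(y) || !nzchar(y)) NA else {
      mn <- if (is.na(m) || !nzchar(m)) "01" else {
        mi <- match(tolower(m), tolower(month.abb))
        if (!is.na(mi)) sprintf("%02d", mi) else sprintf("%02d", as.integer(m))
      }
      dn <- if (is.na(d) || !nzchar(d)) "01" else sprintf("%02d", as.integer(d))
      sprintf("%s-%s-%s", y, mn, dn)
    }
    ncts <- xml2::xml_text(xml2::xml_find_all(
      a, ".//DataBankList/DataBank[DataBankName='ClinicalTrials.gov']//AccessionNumber"
    ))
    study_record(
      study_id = pmid, kind = "publication", title = title, abstract = abstract,
      pub_date = pub_date,
      nct_link = if (length(ncts)) ncts[[1]] else NULL
    )
  })
}

#' Map a ClinicalTrials.gov v2 study JSON onto a registry study record
#'
#' Reader adapter for the v2 API's study objects: identification, status
#' dates, conditions, arms/interventions, and design modules map onto a
#' `trial_registry`-kind [study_record()] carrying [registry_data()].
#'
#' @param json Path to a JSON file or a single JSON string.
#' @return A [study_record()] of kind `"trial_registry"`.
#' @export
read_ctgov_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ps <- obj$protocolSection %||% stop_litmine("read_ctgov_json: no protocolSection", "parse_error")
  nct <- ps$identificationModule$nctId %||% stop_litmine("read_ctgov_json: no nctId", "parse_error")
  title <- ps$identificationModule$briefTitle %||% ""
  summary <- ps$descriptionModule$briefSummary %||% ""
  date <- ps$statusModule$studyFirstSubmitDate %||% NA
  arms <- lapply(ps$armsInterventionsModule$armGroups %||% list(), function(g) {
    arm_record(
      label = g$label, arm_type = g$type %||% "EXPERIMENTAL",
      description = g$description %||% "",
      intervention_names = unlist(g$interventionNames, use.names = FALSE) %||% character()
    )
  })
  truth <- registry_data(
    conditions = unlist(ps$conditionsModule$conditions, use.names = FALSE) %||% character(),
    interventions = unique(unlist(lapply(
      ps$armsInterventionsModule$interventions %||% list(),
      function(iv) iv$name
    ), use.names = FALSE)) %||% character(),
    enrollment = ps$designModule$enrollmentInfo$count %||% 0L,
    study_type = ps$designModule$studyType %||% "INTERVENTIONAL",
    arms = arms
  )
  study_record(
    study_id = nct, kind = "trial_registry", title = title, abstract = summary,
    pub_date = date, registry_truth = truth
  )
}
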