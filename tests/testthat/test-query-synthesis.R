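test_that("term sets trim, deduplicate, and truncate to ten terms", {
  ts <- term_set("s1", population_terms = sprintf("p%d", 1:12),
                 intervention_terms = c(" a ", "a", "b"))
  expect_length(ts$population_terms, 10)
  expect_equal(ts$population_terms, sprintf("p%d", 1:10))
  expect_equal(ts$intervention_terms, c("a", "b"))
  expect_error(term_set("s1", character(), "i"), "empty population")
  expect_error(term_set("s1", "p", c("", "  ")), "empty intervention")
})

test_that("extract_terms parses backend output into a term set", {
  corpus <- cached_corpus()
  backend <- oracle_backend(corpus)
  sid <- corpus$inclusion_truth[[1]][1]
  study <- corpus$studies[[sid]]
  ts <- extract_terms(study, backend)
  expect_s3_class(ts, "term_set")
  expect_setequal(ts$population_terms, study$planted_terms$population)
  expect_setequal(ts$intervention_terms, study$planted_terms$intervention)
  # backend emitting 12 population terms: first 10 kept after dedup
  noisy12 <- mock_backend(paste0(
    '```json\n{"population": [',
    paste(sprintf('"t%d"', 1:12), collapse = ","),
    '], "intervention": ["i1", "i1", "i2"]}\n```'
  ))
  ts2 <- extract_terms(study, noisy12)
  expect_equal(ts2$population_terms, sprintf("t%d", 1:10))
  expect_equal(ts2$intervention_terms, c("i1", "i2"))
  expect_error(extract_terms(study, mock_backend("not json at all {")),
               class = "litmine_parse_error")
})

test_that("assembled query has the two-level OR-of-AND structure", {
  ts1 <- term_set("s1", c("p1", "p2"), "i1")
  q <- assemble_query(list(ts1))
  # And[ Or[ And[p1, p2] ], Or[ i1 ] ]
  expect_s3_class(q, "bq_and")
  expect_length(q$children, 2)
  sp <- q$children[[1]]
  si <- q$children[[2]]
  expect_s3_class(sp, "bq_or")
  expect_length(sp$children, 1)
  expect_equal(vapply(sp$children[[1]]$children, function(t) t$text, character(1)),
               c("p1", "p2"))
  expect_equal(si$children[[1]]$children[[1]]$text, "i1")

  ts2 <- term_set("s2", "p3", c("i2", "i3"))
  q2 <- assemble_query(list(ts1, ts2))
  expect_length(q2$children[[1]]$children, 2)
  expect_length(q2$children[[2]]$children, 2)
})

test_that("assembled oracle query retrieves every source study", {
  corpus <- cached_corpus()
  backend <- oracle_backend(corpus)
  for (rid in names(corpus$reviews)) {
    truth <- corpus$inclusion_truth[[rid]]
    termsets <- lapply(truth, function(sid) extract_terms(corpus$studies[[sid]], backend))
    q <- assemble_query(termsets)
    matches <- evaluate_query(q, corpus)
    expect_true(all(truth %in% matches), label = sprintf("review %s", rid))
  }
})

test_that("assembly is invariant to term order within a study", {
  corpus <- cached_corpus()
  sid <- corpus$inclusion_truth[[1]][1]
  pt <- corpus$studies[[sid]]$planted_terms
  q_fwd <- assemble_query(list(term_set(sid, pt$population, pt$intervention)))
  q_rev <- assemble_query(list(term_set(sid, rev(pt$population), rev(pt$intervention))))
  expect_setequal(evaluate_query(q_fwd, corpus), evaluate_query(q_rev, corpus))
})

test_that("recall filter keeps at the threshold and drops below it", {
  corpus <- cached_corpus()
  rid <- names(corpus$reviews)[1]
  truth <- corpus$inclusion_truth[[rid]]
  backend <- oracle_backend(corpus)
  termsets <- lapply(truth, function(sid) extract_terms(corpus$studies[[sid]], backend))
  q <- assemble_query(termsets)
  verdict <- filter_by_recall(q, corpus, truth)
  expect_true(verdict$keep)
  expect_equal(verdict$recall, 1)
  # no-match query drops
  none <- filter_by_recall(bq_term("zzzznotaterm"), corpus, truth)
  expect_false(none$keep)
  expect_equal(none$recall, 0)
  expect_error(filter_by_recall(q, corpus, character()), "empty truth")
})

test_that("recall filter boundary is inclusive-keep at exactly 0.2", {
  # constructed pool: 100 truth ids, query matching exactly 19 / 20 / 21
  studies <- lapply(1:100, function(i) {
    study_record(sprintf("t%03d", i), "publication",
                 title = if (i <= 19) "hit nineteen" else if (i <= 20) "hit twenty"
                         else if (i <= 21) "hit twentyone" else "miss",
                 abstract = "filler", pub_date = "2019-01-01")
  })
  corpus <- linked_corpus(list(), studies, list())
  truth <- sprintf("t%03d", 1:100)
  q19 <- bq_term("nineteen")
  q20 <- bq_or(bq_term("nineteen"), bq_term("twenty"))
  q21 <- bq_or(bq_term("nineteen"), bq_term("twenty"), bq_term("twentyone"))
  v19 <- filter_by_recall(q19, corpus, truth)
  v20 <- filter_by_recall(q20, corpus, truth)
  v21 <- filter_by_recall(q21, corpus, truth)
  expect_equal(v19$recall, 0.19)
  expect_false(v19$keep)
  expect_equal(v20$recall, 0.20)
  expect_true(v20$keep)   # "below 0.2" is dropped, so exactly 0.2 keeps
  expect_equal(v21$recall, 0.21)
  expect_true(v21$keep)
})

test_that("review-level query generation hits full recall with the oracle", {
  corpus <- cached_corpus()
  backend <- oracle_backend(corpus)
  for (rid in names(corpus$reviews)) {
    review <- corpus$reviews[[rid]]
    q <- generate_query(review$pico, backend, review_id = rid)
    verdict <- filter_by_recall(q, corpus, corpus$inclusion_truth[[rid]])
    expect_equal(verdict$recall, 1, label = sprintf("review %s", rid))
  }
})

test_that("generation fails loudly when a keyword group is missing", {
  corpus <- cached_corpus()
  pico <- corpus$reviews[[1]]$pico
  no_int <- mock_backend('```json\n{"population": ["p1"]}\n```')
  expect_error(generate_query(pico, no_int), class = "litmine_parse_error")
  # raw output travels with the condition
  err <- tryCatch(generate_query(pico, no_int), error = identity)
  expect_true(!is.null(err$raw_output) || grepl("keyword group", conditionMessage(err)))
})

test_that("fixed backend and seed give identical query trees", {
  corpus <- cached_corpus()
  rid <- names(corpus$reviews)[1]
  nb <- noisy_oracle_backend(corpus, error_rate = 0.5, seed = 9)
  q1 <- generate_query(corpus$reviews[[rid]]$pico, nb, seed = 4, review_id = rid)
  q2 <- generate_query(corpus$reviews[[rid]]$pico, nb, seed = 4, review_id = rid)
  expect_identical(serialize_pubmed(q1), serialize_pubmed(q2))
  q3 <- generate_query(corpus$reviews[[rid]]$pico, nb, seed = 5, review_id = rid)
  expect_false(identical(serialize_pubmed(q1), serialize_pubmed(q3)))
})

test_that("a one-run ensemble equals generate-plus-retrieve", {
  corpus <- cached_corpus()
  rid <- names(corpus$reviews)[1]
  backend <- oracle_backend(corpus)
  hits1 <- ensemble_generate(corpus$reviews[[rid]]$pico, backend, corpus,
                             n_runs = 1, limit = 100, seed = 1, review_id = rid)
  q <- generate_query(corpus$reviews[[rid]]$pico, backend, seed = 1, review_id = rid)
  expect_identical(hits1, retrieve(q, corpus, limit = 100))
})

test_that("ensemble union deduplicates keeping first occurrence", {
  # two runs returning [a,b] then [b,c] must aggregate to [a,b,c]
  studies <- list(
    study_record("a", "publication", "first run hit", "alpha beta", pub_date = "2020-03-01"),
    study_record("b", "publication", "both runs hit", "alpha beta gamma", pub_date = "2020-02-01"),
    study_record("c", "publication", "second run hit", "gamma delta", pub_date = "2020-01-01")
  )
  corpus <- linked_corpus(list(), studies, list())
  backend <- mock_backend(c(
    '```json\n{"population": ["alpha"], "intervention": ["beta"]}\n```',
    '```json\n{"population": ["gamma"], "intervention": ["gamma"]}\n```'
  ))
  hits <- ensemble_generate(pico_frame("x", "y"), backend, corpus,
                            n_runs = 2, limit = 10)
  expect_equal(hits, c("a", "b", "c"))
})

test_that("ensemble recall dominates the best single run and is monotone", {
  corpus <- cached_corpus()
  rid <- names(corpus$reviews)[2]
  truth <- corpus$inclusion_truth[[rid]]
  pico <- corpus$reviews[[rid]]$pico
  nb <- noisy_oracle_backend(corpus, error_rate = 0.35, seed = 21)
  single_recalls <- vapply(0:9, function(run) {
    q <- tryCatch(generate_query(pico, nb, seed = 1 + run, review_id = rid),
                  error = function(e) NULL)
    if (is.null(q)) return(0)
    length(intersect(retrieve(q, corpus, limit = 500), truth)) / length(truth)
  }, numeric(1))
  ens <- ensemble_generate(pico, nb, corpus, n_runs = 10, limit = 500,
                           seed = 1, review_id = rid)
  ens_recall <- length(intersect(ens, truth)) / length(truth)
  expect_gte(ens_recall, max(single_recalls))
  # monotone in the number of runs
  recalls_by_runs <- vapply(c(1, 2, 5, 10), function(n) {
    h <- ensemble_generate(pico, nb, corpus, n_runs = n, limit = 500,
                           seed = 1, review_id = rid)
    length(intersect(h, truth)) / length(truth)
  }, numeric(1))
  expect_true(all(diff(recalls_by_runs) >= 0))
})

test_that("ensemble skips failed runs and errors only when all fail", {
  corpus <- cached_corpus(n_reviews = 2, included_per_review = 2,
                          distractors_per_review = 5, seed = 41)
  pico <- corpus$reviews[[1]]$pico
  half_bad <- mock_backend(c(
    "garbage {{{",
    '```json\n{"population": ["alpha"], "intervention": ["beta"]}\n```'
  ))
  expect_warning(
    hits <- ensemble_generate(pico, half_bad, corpus, n_runs = 2, limit = 10),
    "skipped"
  )
  expect_type(hits, "character")
  all_bad <- mock_backend("garbage {{{")
  expect_error(
    suppressWarnings(ensemble_generate(pico, all_bad, corpus, n_runs = 3, limit = 10)),
    class = "litmine_parse_error"
  )
})
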