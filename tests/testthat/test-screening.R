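test_that("label scores follow the four-level map and reject strangers", {
  expect_equal(label_to_score("YES"), 1)
  expect_equal(label_to_score("PARTIAL"), 0.5)
  expect_equal(label_to_score("UNCERTAIN"), 0)
  expect_equal(label_to_score("NO"), -1)
  expect_error(label_to_score("maybe"), class = "litmine_label")
  expect_error(label_to_score("yes"), class = "litmine_label")
})

test_that("aggregation is the arithmetic mean of criterion scores", {
  expect_equal(aggregate_score(c("YES", "YES")), 1)
  expect_equal(aggregate_score(c("YES", "NO")), 0)
  expect_equal(aggregate_score(c("YES", "PARTIAL", "UNCERTAIN", "NO")), 0.125)
  expect_error(aggregate_score(character()), class = "litmine_aggregation")
  # exhaustive agreement with direct arithmetic for all multisets up to size 4
  labels <- c("YES", "PARTIAL", "UNCERTAIN", "NO")
  for (n in 1:4) {
    grids <- expand.grid(rep(list(labels), n), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grids))) {
      combo <- unlist(grids[i, ], use.names = FALSE)
      expect_equal(aggregate_score(combo), direct_score(combo))
    }
  }
})

test_that("upgrading any single label never decreases the final score", {
  ladder <- c("NO", "UNCERTAIN", "PARTIAL", "YES")
  labels <- c("YES", "PARTIAL", "UNCERTAIN", "NO")
  grids <- expand.grid(rep(list(labels), 3), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grids))) {
    combo <- unlist(grids[i, ], use.names = FALSE)
    for (pos in seq_along(combo)) {
      lvl <- match(combo[pos], ladder)
      if (lvl < length(ladder)) {
        upgraded <- combo
        upgraded[pos] <- ladder[lvl + 1]
        expect_gte(aggregate_score(upgraded), aggregate_score(combo))
      }
    }
  }
})

test_that("final scores are bounded with extremes only at all-NO / all-YES", {
  labels <- c("YES", "PARTIAL", "UNCERTAIN", "NO")
  grids <- expand.grid(rep(list(labels), 4), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grids))) {
    combo <- unlist(grids[i, ], use.names = FALSE)
    s <- aggregate_score(combo)
    expect_gte(s, -1)
    expect_lte(s, 1)
    if (s == 1) expect_true(all(combo == "YES"))
    if (s == -1) expect_true(all(combo == "NO"))
  }
})

test_that("oracle assessment scores included studies at exactly one", {
  corpus <- cached_corpus()
  backend <- oracle_backend(corpus)
  rid <- names(corpus$reviews)[1]
  criteria <- review_criteria(corpus$reviews[[rid]])
  sid <- corpus$inclusion_truth[[rid]][1]
  res <- assess_study(criteria, corpus$studies[[sid]], backend, review_id = rid)
  expect_s3_class(res, "eligibility_result")
  expect_equal(res$final_score, 1)
  expect_equal(nrow(res$assessments), length(criteria))
  expect_true(all(res$assessments$label == "YES"))
  # distractor: all NO
  distractor <- setdiff(names(corpus$studies),
                        unlist(corpus$inclusion_truth, use.names = FALSE))[1]
  res_d <- assess_study(criteria, corpus$studies[[distractor]], backend, review_id = rid)
  expect_equal(res_d$final_score, -1)
})

test_that("missing criterion answers degrade to UNCERTAIN with a warning", {
  corpus <- cached_corpus()
  rid <- names(corpus$reviews)[1]
  criteria <- review_criteria(corpus$reviews[[rid]])
  stopifnot(length(criteria) == 4)
  sid <- corpus$inclusion_truth[[rid]][1]
  three <- mock_backend(analysis_json(c("YES", "YES", "YES")))
  expect_warning(
    res <- assess_study(criteria, corpus$studies[[sid]], three, review_id = rid),
    "unparsed"
  )
  expect_equal(res$assessments$label, c("YES", "YES", "YES", "UNCERTAIN"))
  expect_equal(res$assessments$rationale[4], "unparsed")
  expect_equal(res$final_score, 3 / 4)
  # entirely unparseable output: every criterion UNCERTAIN, score 0
  expect_warning(
    res0 <- assess_study(criteria, corpus$studies[[sid]], mock_backend("{{{"),
                         review_id = rid),
    "unparsed"
  )
  expect_equal(res0$final_score, 0)
})

test_that("zero-rate noisy oracle reproduces the oracle exactly", {
  corpus <- cached_corpus()
  rid <- names(corpus$reviews)[1]
  criteria <- review_criteria(corpus$reviews[[rid]])
  sid <- corpus$inclusion_truth[[rid]][1]
  clean <- assess_study(criteria, corpus$studies[[sid]], oracle_backend(corpus),
                        review_id = rid)
  noisy0 <- assess_study(criteria, corpus$studies[[sid]],
                         noisy_oracle_backend(corpus, error_rate = 0, seed = 1),
                         review_id = rid, seed = 99)
  expect_identical(clean$assessments, noisy0$assessments)
})

test_that("candidate pool truncates, fills, deduplicates, and respects time", {
  corpus <- cached_corpus()
  rid <- names(corpus$reviews)[1]
  review <- corpus$reviews[[rid]]
  truth <- corpus$inclusion_truth[[rid]]
  backend <- oracle_backend(corpus)
  q <- generate_query(review$pico, backend, review_id = rid)
  primary <- retrieve(q, corpus, limit = 3000)

  # truncation when primary hits exceed the pool size
  small <- build_candidate_pool(review, corpus, primary, pool_size = 3)
  timely_primary <- primary[vapply(primary, function(s) {
    isTRUE(corpus$studies[[s]]$pub_date < review$pub_date)
  }, logical(1))]
  expect_equal(small, utils::head(timely_primary, 3))

  # empty primary hits: pool filled entirely from single-element queries
  filled <- suppressMessages(
    build_candidate_pool(review, corpus, character(), pool_size = 50)
  )
  expect_gt(length(filled), 0)
  expect_true(all(truth %in% filled))

  # overlapping primary and fill hits appear once, primary position kept
  pool <- suppressMessages(
    build_candidate_pool(review, corpus, primary, pool_size = 50)
  )
  expect_equal(anyDuplicated(pool), 0L)
  expect_equal(pool[seq_along(timely_primary)], timely_primary)

  # everything predates the review
  for (sid in pool) {
    expect_true(corpus$studies[[sid]]$pub_date < review$pub_date)
  }
})

test_that("ranking is by descending score with ascending-id ties", {
  mk <- function(id, score) {
    structure(list(study_id = id,
                   assessments = tibble::tibble(
                     element = "P", criterion = "c", role = "inclusion",
                     label = "YES", rationale = "", score = score
                   ),
                   final_score = score),
              class = "eligibility_result")
  }
  ranked <- rank_candidates(list(mk("s2", 0.5), mk("s1", 1), mk("s3", -1), mk("s0", 0.5)))
  expect_equal(vapply(ranked, function(r) r$study_id, character(1)),
               c("s1", "s0", "s2", "s3"))
})

test_that("oracle screening puts every truth study in the top ranks", {
  corpus <- cached_corpus()
  backend <- oracle_backend(corpus)
  for (rid in names(corpus$reviews)) {
    truth <- corpus$inclusion_truth[[rid]]
    ranked <- run_screening_pipeline(corpus, rid, backend, pool_size = 60, limit = 500)
    expect_equal(attr(ranked, "recall"), 1, label = sprintf("review %s", rid))
    expect_setequal(utils::head(ranked$study_id, length(truth)), truth)
  }
})

test_that("score stratification covers every result exactly once", {
  mk <- function(id, score) {
    structure(list(study_id = id, assessments = tibble::tibble(),
                   final_score = score),
              class = "eligibility_result")
  }
  res <- list(mk("a", 1), mk("b", -1), mk("c", 0), mk("d", 0.75),
              mk("e", -0.5), mk("f", 0.7499))
  df <- stratify_by_score(res)
  expect_equal(nrow(df), 6)
  expect_equal(df$band[df$study_id == "a"], factor("predicted_true",
               levels = levels(df$band)))
  expect_equal(as.character(df$band[df$study_id == "b"]), "predicted_false")
  expect_equal(as.character(df$band[df$study_id == "c"]), "middle")
  expect_equal(as.character(df$band[df$study_id == "d"]), "predicted_true")
  expect_equal(as.character(df$band[df$study_id == "e"]), "predicted_false")
  expect_equal(as.character(df$band[df$study_id == "f"]), "middle")
  expect_false(any(is.na(df$band)))
})

test_that("tidiers expose assessments and summaries", {
  corpus <- cached_corpus()
  rid <- names(corpus$reviews)[1]
  criteria <- review_criteria(corpus$reviews[[rid]])
  sid <- corpus$inclusion_truth[[rid]][1]
  res <- assess_study(criteria, corpus$studies[[sid]], oracle_backend(corpus),
                      review_id = rid)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(criteria))
  gl <- glance(res)
  expect_equal(gl$final_score, 1)
  expect_equal(gl$n_criteria, length(criteria))
})
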