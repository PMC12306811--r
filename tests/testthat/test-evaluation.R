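test_that("recall at k counts truth hits in the top k", {
  expect_equal(recall_at_k(c("a", "x", "b"), truth = c("a", "b"), k = 2), 0.5)
  expect_equal(recall_at_k(c("a", "b", "x"), truth = c("a", "b"), k = 3), 1)
  expect_equal(recall_at_k(c("x", "y"), truth = c("a", "b"), k = 2), 0)
  # shorter ranking than k: whole list used
  expect_equal(recall_at_k("a", truth = c("a", "b"), k = 10), 0.5)
  expect_error(recall_at_k(c("a"), truth = character(), k = 1), "empty truth")
  expect_error(recall_at_k(c("a"), truth = "a", k = 0), "positive integer")
})

test_that("recall agrees with brute-force set intersection for every k", {
  withr::with_seed(500, {
    for (rep in 1:5) {
      universe <- sprintf("s%03d", 1:100)
      ranked <- sample(universe)
      truth <- sample(universe, 17)
      for (k in 1:100) {
        brute <- length(intersect(ranked[1:k], truth)) / length(truth)
        expect_equal(recall_at_k(ranked, truth, k), brute)
      }
    }
  })
})

test_that("recall is non-decreasing in k", {
  withr::with_seed(501, {
    ranked <- sample(sprintf("s%02d", 1:50))
    truth <- sample(ranked, 9)
    recalls <- vapply(1:50, function(k) recall_at_k(ranked, truth, k), numeric(1))
    expect_true(all(diff(recalls) >= 0))
  })
})

test_that("recall at truth size is the k = |truth| special case", {
  withr::with_seed(502, {
    for (rep in 1:10) {
      ranked <- sample(sprintf("s%02d", 1:60))
      truth <- sample(ranked, sample(2:15, 1))
      expect_equal(recall_at_truth_size(ranked, truth),
                   recall_at_k(ranked, truth, k = length(truth)))
    }
  })
  # perfect ranking: 1; truth pushed past its own size: 0
  truth <- c("a", "b", "c")
  expect_equal(recall_at_truth_size(c("a", "b", "c", "x"), truth), 1)
  expect_equal(recall_at_truth_size(c(sprintf("x%d", 1:10), truth), truth), 0)
})

test_that("exact numeric matching passes the normalisation parse table", {
  expect_true(exact_numeric_match("1,204", 1204))
  expect_true(exact_numeric_match("12.50", 12.5))
  expect_true(exact_numeric_match("12.5 years", 12.5))
  expect_true(exact_numeric_match("45%", 45))
  expect_true(exact_numeric_match(250, 250))
  expect_false(exact_numeric_match("12.6", 12.5))
  expect_warning(ok <- exact_numeric_match("none given", 5), "unparseable")
  expect_false(ok)
  expect_error(exact_numeric_match("5", Inf), "finite")
})

test_that("soft matching is reflexive, symmetric, and thresholded", {
  emb <- ngram_embedding_backend()
  expect_true(soft_text_match("atrial fibrillation", "atrial fibrillation", emb))
  expect_equal(attr(soft_text_match("same", "same", emb), "similarity"), 1)
  a <- "metformin treatment arm"
  b <- "metformin therapy group"
  expect_equal(attr(soft_text_match(a, b, emb), "similarity"),
               attr(soft_text_match(b, a, emb), "similarity"))
  # utterly different strings fall under the threshold
  expect_false(soft_text_match("aaaaaaa", "zzzzzzz", emb))
  expect_error(soft_text_match("", "x", emb), "non-empty")
})

test_that("module cosine equals a hand-computed 3-gram dot product", {
  emb <- ngram_embedding_backend(dim = 4096, n = 3)
  s1 <- "warfarin dose"
  s2 <- "warfarin dosing"
  # independent oracle: count 3-grams by hand on the padded lowercase strings,
  # hash each gram with the same fold, build dense vectors, cosine directly
  grams <- function(s) {
    p <- paste0(" ", tolower(s), " ")
    vapply(1:(nchar(p) - 2), function(i) substr(p, i, i + 2), character(1))
  }
  vec <- function(s) {
    v <- numeric(4096)
    for (g in grams(s)) {
      idx <- litmine:::fnv1a(g) %% 4096 + 1
      v[idx] <- v[idx] + 1
    }
    v
  }
  v1 <- vec(s1)
  v2 <- vec(s2)
  manual <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  module <- attr(soft_text_match(s1, s2, emb), "similarity")
  expect_equal(module, manual, tolerance = 1e-12)
})

test_that("zero-vector embeddings score false with a warning", {
  emb <- ngram_embedding_backend(dim = 64, n = 8)
  # a string shorter than the n-gram window embeds to the zero vector
  expect_warning(ok <- soft_text_match("ab", "abdominal pain", emb), "zero-norm")
  expect_false(isTRUE(ok))
})

test_that("oracle extractions score perfect field accuracy", {
  corpus <- cached_corpus()
  backend <- oracle_backend(corpus)
  sids <- utils::head(unlist(corpus$inclusion_truth, use.names = FALSE), 6)
  for (task in c("characteristics", "arm_design", "participant_stats", "trial_results")) {
    pairs <- lapply(sids, function(sid) {
      study <- corpus$studies[[sid]]
      truth <- study$registry_truth
      req <- switch(task,
        characteristics = NULL,
        arm_design = NULL,
        participant_stats = truth$participant_measures[[1]]$request,
        trial_results = truth$outcome_results[[1]]$request
      )
      pred <- extract_structured(task, req, study, backend)
      truth_side <- switch(task,
        characteristics = list(conditions = truth$conditions,
                               interventions = truth$interventions,
                               enrollment = truth$enrollment,
                               study_type = truth$study_type),
        arm_design = truth$arms,
        participant_stats = {
          rs <- truth$participant_measures[[1]]$results
          tibble::tibble(
            group_id = vapply(rs, function(r) r$group_id, character(1)),
            value = vapply(rs, function(r) r$value, numeric(1)),
            notes = vapply(rs, function(r) r$notes, character(1))
          )
        },
        trial_results = {
          rs <- truth$outcome_results[[1]]$results
          tibble::tibble(
            value = vapply(rs, function(r) r$value, numeric(1)),
            title = vapply(rs, function(r) r$title, character(1))
          )
        }
      )
      list(pred = pred, truth = truth_side)
    })
    acc <- field_accuracy(pairs, task = task)
    if (!is.na(acc$text_accuracy)) expect_equal(acc$text_accuracy, 1, label = task)
    if (!is.na(acc$numeric_accuracy)) expect_equal(acc$numeric_accuracy, 1, label = task)
    expect_equal(acc$overall, 1, label = task)
  }
})

test_that("numeric and text fields are scored separately", {
  truth <- tibble::tibble(value = c(10, 20), title = c("group one", "group two"))
  pred <- tibble::tibble(value = c(99, 77), title = c("group one", "group two"))
  acc <- field_accuracy(list(list(pred = pred, truth = truth)), task = "trial_results")
  expect_equal(acc$numeric_accuracy, 0)
  expect_equal(acc$text_accuracy, 1)
  expect_error(field_accuracy(list(), task = "trial_results"), "empty result")
})

test_that("difficulty bins average recalls and gate the interval at ten", {
  reports <- dplyr::bind_rows(
    tibble::tibble(review_id = sprintf("a%d", 1:9), k = 3, recall = seq(0.1, 0.9, by = 0.1),
                   n_truth = 3),
    tibble::tibble(review_id = sprintf("b%d", 1:12), k = 7,
                   recall = rep(c(0.5, 1), 6), n_truth = 7)
  )
  bins <- bin_by_truth_count(reports, bin_width = 5)
  expect_equal(nrow(bins), 2)
  small <- bins[bins$bin_low == 0, ]
  big <- bins[bins$bin_low == 5, ]
  expect_equal(small$n_reviews, 9)
  expect_equal(small$mean_recall, mean(seq(0.1, 0.9, by = 0.1)))
  expect_true(is.na(small$ci_low))  # interval omitted under ten reviews
  expect_equal(big$n_reviews, 12)
  expect_equal(big$mean_recall, 0.75)
  expect_false(is.na(big$ci_low))
  expect_lt(big$ci_low, 0.75)
  expect_gt(big$ci_high, 0.75)
  # hand-averaged six-report fixture
  fix <- tibble::tibble(review_id = sprintf("c%d", 1:6), k = 2,
                        recall = c(0, 0.5, 1, 1, 0.5, 0), n_truth = 2)
  expect_equal(bin_by_truth_count(fix)$mean_recall, 0.5)
})

test_that("autoplot on recall bins returns a ggplot", {
  reports <- tibble::tibble(review_id = sprintf("r%d", 1:12), k = 3,
                            recall = runif(12), n_truth = 3)
  p <- ggplot2::autoplot(bin_by_truth_count(reports))
  expect_s3_class(p, "ggplot")
})
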