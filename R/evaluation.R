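#' Recall at K
#'
#' Fraction of ground-truth studies appearing in the top `k` of a ranked
#' list. `recall_at_truth_size()` is the strict search variant with
#' `k = |truth|`. When the ranking is shorter than `k` the whole list is
#' used.
#'
#' @param ranked Ordered character vector of study ids.
#' @param truth Non-empty character vector of ground-truth ids.
#' @param k Positive integer cutoff.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' recall_at_k(c("a", "x", "b"), truth = c("a", "b"), k = 2)
recall_at_k <- function(ranked, truth, k) {
  if (!length(truth)) stop_litmine("recall_at_k: empty truth set", "config")
  if (!is_count(k)) stop_litmine("recall_at_k: k must be a positive integer", "config")
  top <- utils::head(ranked, k)
  length(intersect(top, truth)) / length(truth)
}

#' @rdname recall_at_k
#' @export
recall_at_truth_size <- function(ranked, truth) {
  recall_at_k(ranked, truth, k = length(truth))
}

#' Per-review recall report
#'
#' @param review_id Identifier.
#' @param ranked,truth As in [recall_at_k()].
#' @param k Cutoff; defaults to `|truth|`.
#' @return One-row tibble: `review_id`, `k`, `recall`, `n_truth`.
#' @export
recall_report <- function(review_id, ranked, truth, k = length(truth)) {
  tibble(
    review_id = review_id, k = as.integer(k),
    recall = recall_at_k(ranked, truth, k), n_truth = length(truth)
  )
}

.unit_words <- c(
  "years", "year", "months", "month", "weeks", "week", "days", "day",
  "participants", "patients", "subjects", "kg", "mg", "ml", "cm", "mmhg",
  "percent", "points"
)

#' Exact numeric field matching
#'
#' Numeric fields are scored by exact decimal equality after normalising
#' the prediction: thousands separators and percent signs are stripped,
#' surrounding unit words are dropped, and the remaining decimal is
#' parsed. An unparseable prediction scores incorrect (with a warning),
#' never raises.
#'
#' @param pred Predicted value (number or text).
#' @param truth Finite number.
#' @return `TRUE`/`FALSE`.
#' @export
#' @examples
#' exact_numeric_match("1,204", 1204)
#' exact_numeric_match("12.5 years", 12.5)
exact_numeric_match <- function(pred, truth) {
  if (!is.numeric(truth) || length(truth) != 1L || !is.finite(truth)) {
    stop_litmine("exact_numeric_match: truth must be a finite number", "config")
  }
  val <- parse_numeric_field(pred)
  if (is.na(val)) {
    warn(sprintf("exact_numeric_match: unparseable prediction '%s' scored incorrect",
                 paste(pred, collapse = " ")))
    return(FALSE)
  }
  isTRUE(val == truth)
}

#' Soft text matching by embedding cosine
#'
#' A predicted text field is correct iff the cosine similarity between its
#' embedding and the truth's embedding reaches `threshold` (inclusive at
#' the boundary). The default embedder is the deterministic hashed
#' character-3-gram backend, so scoring is reproducible offline; an
#' API-embedding backend is a drop-in replacement.
#'
#' @param pred,truth Non-empty strings.
#' @param embedder An embedding backend.
#' @param threshold Cosine threshold (default 0.75).
#' @return `TRUE`/`FALSE`; the cosine is attached as attribute
#'   `"similarity"`.
#' @export
soft_text_match <- function(pred, truth, embedder = ngram_embedding_backend(),
                            threshold = 0.75) {
  if (!is_nonempty_string(pred) || !is_nonempty_string(truth)) {
    stop_litmine("soft_text_match: pred and truth must be non-empty strings", "config")
  }
  sim <- cosine_similarity(backend_embed(embedder, pred),
                           backend_embed(embedder, truth))
  structure(sim >= threshold, similarity = sim)
}

#' Field-level extraction accuracy
#'
#' Scores predicted extraction records against truth records, routing each
#' field by its value kind: numeric fields through
#' [exact_numeric_match()], text/categorical fields through
#' [soft_text_match()]. List-valued fields are scored element-wise,
#' aligned by key where one exists (arm `label`, `group_id`), otherwise by
#' position; a predicted element with no counterpart scores incorrect, and
#' unmatched truth elements count as misses.
#'
#' @param results List of `list(pred = ..., truth = ...)` pairs, where
#'   each side is a record of the same task type (characteristics list,
#'   arm list, or results tibble).
#' @param task Task name routing the comparison.
#' @param schema Field schema for `characteristics` (defaults to
#'   [characteristics_schema()]).
#' @param embedder Embedding backend for text fields.
#' @param threshold Soft-match threshold.
#' @return One-row tibble: `text_accuracy`, `numeric_accuracy`, `overall`,
#'   plus counts `n_text`, `n_numeric`.
#' @export
field_accuracy <- function(results, task, schema = NULL,
                           embedder = ngram_embedding_backend(),
                           threshold = 0.75) {
  task <- match.arg(task, .extraction_tasks)
  if (!length(results)) stop_litmine("field_accuracy: empty result list", "config")
  text_ok <- integer(0)
  num_ok <- integer(0)
  score_text <- function(pred, truth) {
    ok <- if (is.null(pred) || length(pred) == 0L || is.na(pred[1])) FALSE else {
      isTRUE(soft_text_match(as.character(pred), as.character(truth),
                             embedder = embedder, threshold = threshold))
    }
    text_ok <<- c(text_ok, as.integer(ok))
  }
  score_num <- function(pred, truth) {
    ok <- if (is.null(pred) || length(pred) == 0L || is.na(suppressWarnings(parse_numeric_field(pred)))) {
      FALSE
    } else {
      isTRUE(suppressWarnings(exact_numeric_match(pred, truth)))
    }
    num_ok <<- c(num_ok, as.integer(ok))
  }
  for (pair in results) {
    pred <- pair$pred
    truth <- pair$truth
    switch(task,
      characteristics = {
        sch <- schema %||% characteristics_schema()
        for (f in sch) {
          tv <- truth[[f$name]]
          if (is.null(tv)) next
          pv <- pred[[f$name]]
          if (f$value_kind == "number") {
            score_num(pv, tv)
          } else {
            # list-valued text fields element-wise by position
            tv <- as.character(unlist(tv, use.names = FALSE))
            pv <- as.character(unlist(pv, use.names = FALSE))
            for (i in seq_along(tv)) {
              score_text(if (i <= length(pv)) pv[i] else NA_character_, tv[i])
            }
          }
        }
      },
      arm_design = {
        tl <- vapply(truth, function(a) a$label, character(1))
        pl <- vapply(pred, function(a) a$label, character(1))
        for (i in seq_along(truth)) {
          j <- match(tl[i], pl) # key alignment by arm label
          p <- if (!is.na(j)) pred[[j]] else NULL
          score_text(p$label, truth[[i]]$label)
          score_text(p$arm_type, truth[[i]]$arm_type)
          score_text(p$description, truth[[i]]$description)
          tn <- truth[[i]]$intervention_names
          pn <- p$intervention_names %||% character()
          for (k in seq_along(tn)) {
            score_text(if (k <= length(pn)) pn[k] else NA_character_, tn[k])
          }
        }
      },
      participant_stats = {
        for (i in seq_len(nrow(truth))) {
          j <- match(truth$group_id[i], pred$group_id) # key alignment
          score_num(if (!is.na(j)) pred$value[j] else NA_real_, truth$value[i])
          if (!is.na(truth$notes[i]) && nzchar(truth$notes[i])) {
            score_text(if (!is.na(j)) pred$notes[j] else NA_character_, truth$notes[i])
          }
        }
      },
      trial_results = {
        for (i in seq_len(nrow(truth))) { # positional alignment: no key
          score_num(if (i <= nrow(pred)) pred$value[i] else NA_real_, truth$value[i])
          score_text(if (i <= nrow(pred)) pred$title[i] else NA_character_, truth$title[i])
        }
      }
    )
  }
  n_text <- length(text_ok)
  n_num <- length(num_ok)
  tibble(
    text_accuracy = if (n_text) mean(text_ok) else NA_real_,
    numeric_accuracy = if (n_num) mean(num_ok) else NA_real_,
    overall = mean(c(text_ok, num_ok)),
    n_text = n_text, n_numeric = n_num
  )
}

#' Bin per-review recalls by truth-set size
#'
#' Groups recall reports into difficulty bins of `bin_width` ground-truth
#' studies (`[0,5)`, `[5,10)`, ...) and reports the mean recall per bin
#' with a normal-approximation 95% confidence interval. The interval is
#' omitted (NA) for bins holding fewer than ten reviews.
#'
#' @param reports Tibble of recall reports (needs `recall`, `n_truth`).
#' @param bin_width Bin width in number of target studies (default 5).
#' @return A `recall_bins` tibble: `bin`, `bin_low`, `n_reviews`,
#'   `mean_recall`, `ci_low`, `ci_high`.
#' @export
bin_by_truth_count <- function(reports, bin_width = 5) {
  stopifnot(is.data.frame(reports))
  if (!nrow(reports)) {
    return(structure(tibble(bin = character(), bin_low = integer(),
                            n_reviews = integer(), mean_recall = numeric(),
                            ci_low = numeric(), ci_high = numeric()),
                     class = c("recall_bins", "tbl_df", "tbl", "data.frame")))
  }
  out <- reports |>
    dplyr::mutate(bin_low = (.data$n_truth %/% bin_width) * bin_width) |>
    dplyr::group_by(.data$bin_low) |>
    dplyr::summarise(
      n_reviews = dplyr::n(),
      mean_recall = mean(.data$recall),
      se = stats::sd(.data$recall) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin = sprintf("[%d-%d)", .data$bin_low, .data$bin_low + bin_width),
      ci_low = ifelse(.data$n_reviews >= 10,
                      pmax(0, .data$mean_recall - 1.96 * .data$se), NA_real_),
      ci_high = ifelse(.data$n_reviews >= 10,
                       pmin(1, .data$mean_recall + 1.96 * .data$se), NA_real_)
    ) |>
    dplyr::arrange(.data$bin_low) |>
    dplyr::select("bin", "bin_low", "n_reviews", "mean_recall", "ci_low", "ci_high")
  class(out) <- c("recall_bins", class(out))
  out
}
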