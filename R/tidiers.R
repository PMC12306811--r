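#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for eligibility results
#'
#' `tidy()` returns the per-criterion assessment rows; `glance()` a
#' one-row summary with the final eligibility score.
#'
#' @param x An `eligibility_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eligibility_result <- function(x, ...) {
  dplyr::mutate(x$assessments, study_id = x$study_id, .before = 1)
}

#' @rdname tidy.eligibility_result
#' @export
glance.eligibility_result <- function(x, ...) {
  tibble(
    study_id = x$study_id,
    final_score = x$final_score,
    n_criteria = nrow(x$assessments),
    n_yes = sum(x$assessments$label == "YES"),
    n_no = sum(x$assessments$label == "NO")
  )
}

#' @rdname tidy.eligibility_result
#' @export
tidy.ranked_eligibility <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.eligibility_result
#' @export
glance.linked_corpus <- function(x, ...) {
  n_truth <- lengths(x$inclusion_truth)
  tibble(
    n_reviews = length(x$reviews),
    n_studies = length(x$studies),
    n_linked = sum(vapply(x$studies, function(s) !is.null(s$registry_truth), logical(1))),
    min_truth = if (length(n_truth)) min(n_truth) else 0L,
    max_truth = if (length(n_truth)) max(n_truth) else 0L
  )
}
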