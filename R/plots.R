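#' Plot recall by difficulty bin
#'
#' Bar chart of mean recall per truth-count bin with 95% confidence
#' intervals where available (bins with fewer than ten reviews have no
#' interval).
#'
#' @param object A `recall_bins` tibble from [bin_by_truth_count()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recall_bins <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$bin, .data$bin_low),
                                       y = .data$mean_recall)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "ground-truth studies per review", y = "mean recall") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the eligibility-score distribution with decision bands
#'
#' Histogram of final eligibility scores coloured by the score band used
#' to compare predictions with expert decisions.
#'
#' @param results List of `eligibility_result`s or a `ranked_eligibility`.
#' @param binwidth Histogram bin width.
#' @return A ggplot.
#' @export
plot_score_bands <- function(results, binwidth = 0.125) {
  df <- stratify_by_score(results)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$final_score, fill = .data$band)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = -1) +
    ggplot2::scale_fill_manual(values = c(
      predicted_false = "firebrick", middle = "grey60", predicted_true = "forestgreen"
    ), drop = FALSE) +
    ggplot2::labs(x = "final eligibility score", y = "studies") +
    ggplot2::theme_minimal()
}

#' Plot instruction-dataset composition
#'
#' Record counts per task and split for a built instruction dataset.
#'
#' @param records Instruction-record tibble with `split` assigned.
#' @return A ggplot.
#' @export
plot_instruction_counts <- function(records) {
  df <- dplyr::count(records, .data$task, .data$split)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task, y = .data$n, fill = .data$split)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "records") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
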