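#' Plot per-ancestry positive rates with confidence intervals
#'
#' Bar chart of the overall positive rate per ancestry group with binomial
#' confidence-interval error bars, and the per-category breakdown
#' (known P/LP, pLoF overlapping known P/LP, novel pLoF) as dodged bars.
#'
#' @param object A `burden_table`.
#' @param level Confidence level for the error bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burden_table <- function(object, level = 0.95, ...) {
  overall <- dplyr::bind_cols(
    object$overall["group"],
    rate_with_ci(object$overall$positives, object$overall$n, level = level)
  )
  cats <- object$categories |>
    dplyr::left_join(object$denominators, by = "group") |>
    dplyr::mutate(rate = .data$count / .data$n)
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = cats,
      ggplot2::aes(x = .data$group, y = .data$rate, fill = .data$category),
      position = "dodge"
    ) +
    ggplot2::geom_pointrange(
      data = overall,
      ggplot2::aes(
        x = .data$group, y = .data$rate,
        ymin = .data$ci_low, ymax = .data$ci_high
      )
    ) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.2f%%", 100 * x)) +
    ggplot2::labs(
      x = "ancestry group", y = "positive rate",
      fill = NULL,
      title = "Qualifying-variant rates by ancestry group",
      subtitle = sprintf(
        "points: overall rate with %d%% CI; bars: category rates",
        round(100 * level)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot relative rate differences against a reference database
#'
#' Bar chart of signed relative differences between cohort and reference
#' per-gene rates, coloured by ancestry group.
#'
#' @param comparison A tibble with columns `gene`, `population` and
#'   `rel_diff` (e.g. a filtered [subset_resolution_report()]).
#' @return A ggplot object.
#' @export
plot_relative_rates <- function(comparison) {
  ggplot2::ggplot(
    comparison,
    ggplot2::aes(x = .data$gene, y = .data$rel_diff, fill = .data$population)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "(cohort - reference) / reference",
      title = "Relative pathogenic-rate difference vs reference"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot reference-subset resolution for one gene and population
#'
#' Side-by-side bars of the cohort rate and the rate in each reference
#' subset, highlighting which subset best matches the cohort.
#'
#' @param report A [subset_resolution_report()] tibble.
#' @param gene,population The gene and population to display.
#' @return A ggplot object.
#' @export
plot_subset_comparison <- function(report, gene, population) {
  rows <- report[report$gene == gene & report$population == population, ]
  if (nrow(rows) == 0) stop("no rows for that gene/population", call. = FALSE)
  bars <- dplyr::bind_rows(
    tibble::tibble(
      source = "cohort", rate = rows$cohort_rate[1], closest = NA
    ),
    tibble::tibble(
      source = paste0("reference: ", rows$subset),
      rate = rows$reference_rate,
      closest = rows$closest
    )
  )
  ggplot2::ggplot(
    bars,
    ggplot2::aes(
      x = .data$source, y = .data$rate,
      fill = dplyr::coalesce(.data$closest, FALSE)
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "P/LP allele rate",
      title = sprintf("%s (%s): cohort vs reference subsets", gene, population)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
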