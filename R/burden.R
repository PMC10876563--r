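#' Count qualifying findings per gene and ancestry group
#'
#' Aggregates a findings table into a burden table: for every panel gene and
#' ancestry group, the number of distinct participants in that group with at
#' least one qualifying finding in that gene, together with the per-group
#' denominators (all genotyped participants, carriers or not) and per-group
#' category totals. The overall per-group positive rate counts distinct
#' participants with a finding in *any* panel gene, so a participant with
#' findings in two genes contributes to both gene cells but only once to the
#' overall rate.
#'
#' Two counting modes are provided. `"participants"` (default) counts
#' distinct carriers, matching participant-level positive-rate reporting;
#' `"alleles"` counts allele instances (1 per heterozygous, 2 per homozygous
#' call), matching allele-count-style tables where participants may
#' contribute more than one instance.
#'
#' @param findings Findings tibble ([qualifying_findings()] output).
#' @param ancestry Tibble with columns `participant_id`, `ancestry`; every
#'   genotyped participant must appear exactly once. Participants carrying a
#'   finding but missing from this table are excluded from all counts and
#'   reported in the diagnostics.
#' @param panel Optional panel tibble; its genes define the table rows (genes
#'   without findings appear with zero counts). Defaults to the genes present
#'   in `findings`.
#' @param mode `"participants"` or `"alleles"`.
#' @return An object of class `burden_table`: a list with elements
#'   `counts` (tibble `gene` x `group` long counts), `denominators`
#'   (`group`, `n`), `overall` (`group`, `positives`, `n`, `rate`),
#'   `categories` (`group`, `category`, `count`), `mode` and `diagnostics`.
#' @export
count_cohort <- function(findings, ancestry, panel = NULL,
                         mode = c("participants", "alleles")) {
  mode <- match.arg(mode)
  if (anyDuplicated(ancestry$participant_id) > 0) {
    stop("participants must have exactly one ancestry label each", call. = FALSE)
  }
  groups <- sort(unique(ancestry$ancestry))
  genes <- sort(unique(if (is.null(panel)) findings$gene else panel$gene))

  labelled <- dplyr::inner_join(findings, ancestry, by = "participant_id")
  missing_ids <- setdiff(findings$participant_id, ancestry$participant_id)
  if (length(missing_ids) > 0) {
    message(
      length(missing_ids),
      " participant(s) with findings lack an ancestry label and were excluded"
    )
  }

  grid <- tidyr::expand_grid(gene = genes, group = groups)
  weight <- function(zyg) ifelse(zyg == "hom_alt", 2L, 1L)

  if (mode == "participants") {
    cell <- labelled |>
      dplyr::distinct(.data$gene, .data$ancestry, .data$participant_id) |>
      dplyr::count(.data$gene, group = .data$ancestry, name = "count")
  } else {
    cell <- labelled |>
      dplyr::group_by(.data$gene, group = .data$ancestry) |>
      dplyr::summarise(count = sum(weight(.data$zygosity)), .groups = "drop")
  }
  counts <- grid |>
    dplyr::left_join(cell, by = c("gene", "group")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))

  denominators <- ancestry |>
    dplyr::count(group = .data$ancestry, name = "n") |>
    dplyr::arrange(.data$group)

  overall_pos <- labelled |>
    dplyr::distinct(.data$ancestry, .data$participant_id) |>
    dplyr::count(group = .data$ancestry, name = "positives")
  overall <- denominators |>
    dplyr::left_join(overall_pos, by = "group") |>
    dplyr::mutate(
      positives = dplyr::coalesce(.data$positives, 0L),
      rate = .data$positives / .data$n
    ) |>
    dplyr::select("group", "positives", "n", "rate")

  categories <- labelled |>
    dplyr::distinct(.data$ancestry, .data$category, .data$participant_id) |>
    dplyr::count(group = .data$ancestry, .data$category, name = "count") |>
    tidyr::complete(
      group = groups,
      category = c("known_plp", "plof_known_overlap", "plof_novel"),
      fill = list(count = 0L)
    )

  structure(
    list(
      counts = counts,
      denominators = denominators,
      overall = overall,
      categories = categories,
      mode = mode,
      diagnostics = list(
        n_missing_ancestry = length(missing_ids),
        missing_ancestry_ids = missing_ids
      )
    ),
    class = "burden_table"
  )
}

#' Spread burden counts to a gene-by-group matrix
#'
#' @param x A `burden_table` or a long counts tibble (`gene`, `group`,
#'   `count`).
#' @return A wide tibble: one row per gene, one column per group.
#' @export
burden_matrix <- function(x) {
  counts <- if (inherits(x, "burden_table")) x$counts else x
  tidyr::pivot_wider(
    counts,
    names_from = "group", values_from = "count", values_fill = 0L
  )
}

#' @export
print.burden_table <- function(x, ...) {
  cat(
    "<burden_table> ", length(unique(x$counts$gene)), " genes x ",
    nrow(x$denominators), " ancestry groups (mode: ", x$mode, ")\n",
    sep = ""
  )
  cat("Overall positive rates:\n")
  print(x$overall)
  invisible(x)
}

#' Tidy a burden table
#'
#' @param x A `burden_table`.
#' @param ... Unused.
#' @return A long tibble with one row per gene x group: `gene`, `group`,
#'   `count`, `n` (group denominator) and `rate`.
#' @export
tidy.burden_table <- function(x, ...) {
  x$counts |>
    dplyr::left_join(x$denominators, by = "group") |>
    dplyr::mutate(rate = .data$count / .data$n)
}

#' One-row summary of a burden table
#'
#' @param x A `burden_table`.
#' @param ... Unused.
#' @return A one-row tibble: number of genes, groups, participants, total
#'   positives and the pooled positive rate.
#' @export
glance.burden_table <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$counts$gene)),
    n_groups = nrow(x$denominators),
    n_participants = sum(x$denominators$n),
    n_positive = sum(x$overall$positives),
    positive_rate = sum(x$overall$positives) / sum(x$denominators$n),
    mode = x$mode
  )
}
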