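#' Gene-level pathogenic allele rates from joined frequency records
#'
#' Summarises P/LP variants joined to a frequency table ([join_frequencies()])
#' into a per-gene rate: the numerator adds up the alternate allele counts of
#' the gene's P/LP variants and the denominator is the maximum total allele
#' number observed among them. Genes whose variants are all absent from the
#' frequency table get `rate = 0` and `flag = "empty"`; genes with rows but
#' no observed alleles (`an = 0` throughout) are flagged `"undefined"`.
#'
#' @param joined_records Output of [join_frequencies()] (any number of
#'   populations/subsets stacked).
#' @return A tibble with one row per gene x population x subset: `gene`,
#'   `population`, `subset`, `numerator`, `denominator`, `rate`, `flag`
#'   (`"ok"`, `"empty"` or `"undefined"`).
#' @export
gene_level_rate <- function(joined_records) {
  joined_records |>
    dplyr::group_by(.data$gene, .data$population, .data$subset) |>
    dplyr::summarise(
      numerator = sum(.data$ac),
      denominator = max(.data$an, 0L),
      n_variants = sum(!.data$absent),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate = ifelse(.data$denominator > 0, .data$numerator / .data$denominator, 0),
      flag = dplyr::case_when(
        .data$n_variants == 0 ~ "empty",
        .data$denominator == 0 ~ "undefined",
        TRUE ~ "ok"
      )
    ) |>
    dplyr::select(-"n_variants")
}

#' Signed relative difference between cohort and reference rates
#'
#' Computes `(cohort - reference) / reference`. When both rates are zero the
#' difference is 0; when the reference rate is zero but the cohort rate is
#' not, the ratio is undefined and `NA` is returned.
#'
#' @param cohort_rate,reference_rate Numeric vectors of rates.
#' @return Numeric vector of signed relative differences (`NA` where
#'   undefined).
#' @examples
#' relative_rate_difference(0.0015, 0.001) # +0.5
#' @export
relative_rate_difference <- function(cohort_rate, reference_rate) {
  if (any(reference_rate < 0, na.rm = TRUE)) {
    stop("reference rates must be non-negative", call. = FALSE)
  }
  dplyr::case_when(
    reference_rate > 0 ~ (cohort_rate - reference_rate) / reference_rate,
    cohort_rate == 0 ~ 0,
    TRUE ~ NA_real_
  )
}

#' Pearson correlation of per-gene rates between two sources
#'
#' Product-moment correlation of per-gene rates across the genes present
#' (with finite rates) in both tables — the concordance summary used to
#' compare cohort-derived and reference-database pathogenic rates.
#'
#' @param gene_rates_a,gene_rates_b Tibbles with columns `gene` and `rate`.
#' @return A one-row tibble: `r`, `n_genes`, `flag` (`"ok"`,
#'   `"zero_variance"`, or `"insufficient_genes"`) and a `genes` list-column
#'   of the genes used. `r` is `NA` unless `flag == "ok"`.
#' @export
rate_correlation <- function(gene_rates_a, gene_rates_b) {
  paired <- dplyr::inner_join(
    dplyr::select(gene_rates_a, "gene", rate_a = "rate"),
    dplyr::select(gene_rates_b, "gene", rate_b = "rate"),
    by = "gene"
  ) |>
    dplyr::filter(is.finite(.data$rate_a), is.finite(.data$rate_b))
  if (nrow(paired) < 3) {
    return(tibble::tibble(
      r = NA_real_, n_genes = nrow(paired), flag = "insufficient_genes",
      genes = list(paired$gene)
    ))
  }
  if (stats::sd(paired$rate_a) == 0 || stats::sd(paired$rate_b) == 0) {
    return(tibble::tibble(
      r = NA_real_, n_genes = nrow(paired), flag = "zero_variance",
      genes = list(paired$gene)
    ))
  }
  tibble::tibble(
    r = stats::cor(paired$rate_a, paired$rate_b),
    n_genes = nrow(paired),
    flag = "ok",
    genes = list(paired$gene)
  )
}

#' Compare a cohort rate against reference subsets
#'
#' Reference databases ship defined sub-cohorts (e.g. a non-cancer subset
#' excluding cancer-ascertained samples, or a non-TopMed subset). For each
#' gene x population, this report lays the cohort rate alongside the rate in
#' each available reference subset and flags the subset whose rate is
#' closest to the cohort's (smallest absolute relative difference). Exact
#' ties are broken by subset name and noted.
#'
#' @param cohort_rates Tibble with columns `gene`, `population`, `rate`
#'   (cohort-side rates).
#' @param reference_rates Tibble with columns `gene`, `population`,
#'   `subset`, `rate` ([gene_level_rate()] output).
#' @return A tibble with one row per gene x population x subset:
#'   `reference_rate`, `cohort_rate`, `rel_diff`, `closest` (logical),
#'   `tie` (logical; `TRUE` on rows involved in a broken tie). Rows where
#'   only one subset is available carry `closest = NA`.
#' @export
subset_resolution_report <- function(cohort_rates, reference_rates) {
  joined <- reference_rates |>
    dplyr::select("gene", "population", "subset", reference_rate = "rate") |>
    dplyr::inner_join(
      dplyr::select(cohort_rates, "gene", "population", cohort_rate = "rate"),
      by = c("gene", "population")
    ) |>
    dplyr::mutate(
      rel_diff = relative_rate_difference(.data$cohort_rate, .data$reference_rate)
    )
  joined |>
    dplyr::group_by(.data$gene, .data$population) |>
    dplyr::arrange(abs(.data$rel_diff), .data$subset, .by_group = TRUE) |>
    dplyr::mutate(
      n_subsets = dplyr::n(),
      closest = dplyr::if_else(
        .data$n_subsets < 2, NA,
        dplyr::row_number() == 1L
      ),
      tie = .data$n_subsets >= 2 &
        sum(abs(.data$rel_diff) == min(abs(.data$rel_diff), na.rm = TRUE),
          na.rm = TRUE
        ) > 1 &
        !is.na(.data$rel_diff) &
        abs(.data$rel_diff) == min(abs(.data$rel_diff), na.rm = TRUE)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_subsets") |>
    dplyr::arrange(.data$gene, .data$population, .data$subset)
}

#' Cohort-side per-gene allele rates from qualifying findings
#'
#' Builds allele-frequency-style per-gene rates from the cohort itself so
#' they are commensurable with reference-database allele counts: the
#' numerator counts allele instances of known-P/LP findings (1 per het, 2
#' per hom) per gene and group, the denominator is twice the group size
#' (autosomal allele number). A participant-rate mode (distinct carriers /
#' participants) is also available and labelled in the output.
#'
#' @param findings Findings tibble ([qualifying_findings()] output).
#' @param ancestry Ancestry label tibble (`participant_id`, `ancestry`).
#' @param mode `"alleles"` (default) or `"participants"`.
#' @param categories Finding categories to include (default `known_plp`).
#' @return A tibble: `gene`, `population`, `rate`, `numerator`,
#'   `denominator`, `mode`.
#' @export
cohort_gene_rates <- function(findings, ancestry,
                              mode = c("alleles", "participants"),
                              categories = "known_plp") {
  mode <- match.arg(mode)
  labelled <- findings |>
    dplyr::filter(.data$category %in% categories) |>
    dplyr::inner_join(ancestry, by = "participant_id")
  denom <- ancestry |>
    dplyr::count(population = .data$ancestry, name = "n_participants")
  if (mode == "alleles") {
    num <- labelled |>
      dplyr::group_by(.data$gene, population = .data$ancestry) |>
      dplyr::summarise(
        numerator = sum(ifelse(.data$zygosity == "hom_alt", 2L, 1L)),
        .groups = "drop"
      )
    denom <- dplyr::mutate(denom, denominator = 2L * .data$n_participants)
  } else {
    num <- labelled |>
      dplyr::distinct(.data$gene, .data$ancestry, .data$participant_id) |>
      dplyr::count(.data$gene, population = .data$ancestry, name = "numerator")
    denom <- dplyr::mutate(denom, denominator = .data$n_participants)
  }
  num |>
    dplyr::inner_join(
      dplyr::select(denom, "population", "denominator"),
      by = "population"
    ) |>
    dplyr::mutate(rate = .data$numerator / .data$denominator, mode = .env$mode)
}
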