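#' Read a curated variant-interpretation database
#'
#' Reads a tab-separated curated knowledge base ("VIP"-style: a laboratory
#' database of expert variant interpretations) into a tibble of classified
#' variants. Expected columns: `Chrom`, `Pos`, `Ref`, `Alt`, `Gene`,
#' `Vip_variant_interpretation` (plus optional `Hgvs_c`, `Source`).
#'
#' Interpretation strings must belong to the closed, case-sensitive set
#' `Path`, `LPath`, `VUS`, `Benign`, `LBenign`, `Risk`; anything else is an
#' error rather than being coerced. Rows that duplicate a key with the same
#' classification are collapsed; duplicated keys carrying *conflicting*
#' classifications abort with the offending keys listed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `key`, `gene`, `classification`, `hgvs_c`,
#'   `source`.
#' @seealso [kb_plp()] to restrict to the pathogenic/likely-pathogenic subset.
#' @export
read_vip <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("Chrom", "Pos", "Ref", "Alt", "Gene", "Vip_variant_interpretation")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("VIP file is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  kb <- tibble::tibble(
    key = variant_key(raw$Chrom, raw$Pos, raw$Ref, raw$Alt),
    gene = as.character(raw$Gene),
    classification = as.character(raw$Vip_variant_interpretation),
    hgvs_c = if ("Hgvs_c" %in% names(raw)) as.character(raw$Hgvs_c) else NA_character_,
    source = if ("Source" %in% names(raw)) as.character(raw$Source) else "VIP"
  )
  bad <- setdiff(unique(kb$classification), KB_CLASSIFICATIONS)
  if (length(bad) > 0) {
    stop(
      "unknown interpretation value(s) in Vip_variant_interpretation: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  kb <- dplyr::distinct(kb, .data$key, .data$classification, .keep_all = TRUE)
  dup <- kb$key[duplicated(kb$key)]
  if (length(dup) > 0) {
    stop(
      "conflicting classifications for key(s): ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  kb
}

#' Restrict a knowledge base to P/LP variants
#'
#' @param kb A knowledge-base tibble as returned by [read_vip()] or
#'   [filter_clinvar_plp()].
#' @return The rows classified `Path` or `LPath`.
#' @export
kb_plp <- function(kb) {
  dplyr::filter(kb, .data$classification %in% c("Path", "LPath"))
}

#' Derive the ClinVar star rating from a review-status string
#'
#' Implements the standard ClinVar review-status ladder: practice guideline
#' (4), expert panel review (3), multiple concordant submitters (2), a single
#' submitter with assertion criteria or conflicting interpretations (1), and
#' no usable assertion (0). Unrecognized strings map to 0 with a warning so
#' that a schema drift in the input is visible without aborting a run.
#'
#' @param review_status Character vector of verbatim `ReviewStatus` strings.
#' @return An integer vector of star counts in `[0, 4]`.
#' @examples
#' clinvar_stars("practice guideline")
#' clinvar_stars("criteria provided, conflicting interpretations")
#' @export
clinvar_stars <- function(review_status) {
  status <- tolower(trimws(as.character(review_status)))
  map <- c(
    "practice guideline" = 4L,
    "reviewed by expert panel" = 3L,
    "criteria provided, multiple submitters, no conflicts" = 2L,
    "criteria provided, conflicting interpretations" = 1L,
    "criteria provided, single submitter" = 1L,
    "no assertion criteria provided" = 0L,
    "no assertion provided" = 0L,
    "no interpretation for the single variant" = 0L
  )
  stars <- unname(map[status])
  unknown <- is.na(stars) & !is.na(status)
  if (any(unknown)) {
    warning(
      "unrecognized ReviewStatus value(s) mapped to 0 stars: ",
      paste(unique(status[unknown]), collapse = "; "),
      call. = FALSE
    )
    stars[unknown] <- 0L
  }
  stars
}

parse_clinvar_date <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "-", "NA")] <- NA_character_
  d <- as.Date(x, format = "%Y-%m-%d")
  alt <- is.na(d) & !is.na(x)
  d[alt] <- as.Date(x[alt], format = "%b %d, %Y")
  d
}

#' Read a ClinVar variant-summary style TSV
#'
#' Parses the `variant_summary.txt` dialect: tab-separated, one row per
#' variant-assembly pair. Only the columns needed downstream are retained;
#' header names can be remapped through `col_map` for files whose headers
#' differ from the stock ClinVar export.
#'
#' @param path Path to the TSV file.
#' @param col_map Optional named character vector mapping the canonical column
#'   names (`Assembly`, `GeneSymbol`, `ClinicalSignificance`, `ReviewStatus`,
#'   `LastEvaluated`, `Chromosome`, `PositionVCF`, `ReferenceAlleleVCF`,
#'   `AlternateAlleleVCF`) to the headers actually present.
#' @return A tibble with columns `key`, `assembly`, `gene`,
#'   `clinical_significance`, `review_status`, `stars`, `last_evaluated`.
#'   `stars` is derived from `review_status` via [clinvar_stars()];
#'   `last_evaluated` accepts both ISO (`2022-01-22`) and `"Jan 22, 2022"`
#'   style dates, with missing dates kept as `NA`.
#' @export
read_clinvar <- function(path, col_map = NULL) {
  canonical <- c(
    "Assembly", "GeneSymbol", "ClinicalSignificance", "ReviewStatus",
    "LastEvaluated", "Chromosome", "PositionVCF", "ReferenceAlleleVCF",
    "AlternateAlleleVCF"
  )
  map <- stats::setNames(canonical, canonical)
  if (!is.null(col_map)) map[names(col_map)] <- unlist(col_map)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    stop("ClinVar file is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    key = variant_key(
      raw[[map["Chromosome"]]], raw[[map["PositionVCF"]]],
      raw[[map["ReferenceAlleleVCF"]]], raw[[map["AlternateAlleleVCF"]]]
    ),
    assembly = as.character(raw[[map["Assembly"]]]),
    gene = as.character(raw[[map["GeneSymbol"]]]),
    clinical_significance = as.character(raw[[map["ClinicalSignificance"]]]),
    review_status = as.character(raw[[map["ReviewStatus"]]]),
    stars = clinvar_stars(raw[[map["ReviewStatus"]]]),
    last_evaluated = parse_clinvar_date(raw[[map["LastEvaluated"]]])
  )
}

#' Filter ClinVar records to confidently pathogenic variants
#'
#' Applies the star/date/significance filtering scheme used to build the
#' confirmatory P/LP set from a ClinVar export:
#'
#' * GRCh38 assembly records only;
#' * `ClinicalSignificance` exactly one of the six P/LP strings (pathogenic,
#'   likely pathogenic, their combination, each optionally `, risk factor`);
#'   in particular `"Conflicting interpretations of pathogenicity"` never
#'   passes;
#' * two-star records (`"criteria provided, multiple submitters, no
#'   conflicts"`) only when `LastEvaluated` falls on or after `cutoff_date`;
#'   a missing date fails the test and the record is dropped (counted in the
#'   message);
#' * three- and four-star records ("reviewed by expert panel", "practice
#'   guideline") are kept regardless of the evaluation date.
#'
#' @param records A tibble from [read_clinvar()].
#' @param cutoff_date Date before which two-star evaluations are considered
#'   stale. Default `"2016-01-01"`.
#' @return A knowledge-base tibble (`key`, `gene`, `classification`,
#'   `hgvs_c`, `source`) with classification `Path` or `LPath`, suitable for
#'   the same downstream use as [read_vip()] output. Combined
#'   pathogenic/likely-pathogenic significance strings map to `Path`.
#' @export
filter_clinvar_plp <- function(records, cutoff_date = as.Date("2016-01-01")) {
  cutoff_date <- as.Date(cutoff_date)
  sig_ok <- records$clinical_significance %in% CLINVAR_PLP_SIGNIFICANCE
  two_star <- records$stars == 2L &
    tolower(records$review_status) ==
      "criteria provided, multiple submitters, no conflicts"
  date_ok <- !is.na(records$last_evaluated) & records$last_evaluated >= cutoff_date
  keep <- records$assembly == "GRCh38" & sig_ok &
    ((two_star & date_ok) | records$stars >= 3L)

  n_missing_date <- sum(records$assembly == "GRCh38" & sig_ok & two_star &
    is.na(records$last_evaluated))
  if (n_missing_date > 0) {
    message(
      n_missing_date,
      " two-star P/LP record(s) dropped for missing LastEvaluated date"
    )
  }

  kept <- records[keep, , drop = FALSE]
  tibble::tibble(
    key = kept$key,
    gene = kept$gene,
    classification = ifelse(
      startsWith(kept$clinical_significance, "Likely pathogenic"),
      "LPath", "Path"
    ),
    hgvs_c = NA_character_,
    source = "ClinVar"
  ) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
}

#' Read a population allele-frequency table
#'
#' Reads a gnomAD-style per-population, per-subset allele-frequency TSV with
#' columns `Chrom`, `Pos`, `Ref`, `Alt`, `Gene`, `Population`, `Subset`,
#' `AC`, `AN`, `Popmax_AF`. Populations follow the continental labels
#' (`afr`, `amr`, `eas`, `eur`, `mid`, `sas`, `oth`, `all`); subsets are
#' `full`, `non_cancer`, `non_topmed` (defined sub-cohorts of the reference
#' database used to exclude disease-ascertained samples).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `key`, `gene`, `population`, `subset`,
#'   `ac`, `an`, `popmax_af`.
#' @export
read_frequencies <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("Chrom", "Pos", "Ref", "Alt", "Gene", "Population", "Subset", "AC", "AN")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("frequency file is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    key = variant_key(raw$Chrom, raw$Pos, raw$Ref, raw$Alt),
    gene = as.character(raw$Gene),
    population = as.character(raw$Population),
    subset = as.character(raw$Subset),
    ac = as.integer(raw$AC),
    an = as.integer(raw$AN),
    popmax_af = if ("Popmax_AF" %in% names(raw)) as.numeric(raw$Popmax_AF) else NA_real_
  )
  bad_pop <- setdiff(unique(out$population), FREQ_POPULATIONS)
  if (length(bad_pop) > 0) {
    stop("unknown population label(s): ", paste(bad_pop, collapse = ", "),
      call. = FALSE
    )
  }
  bad_sub <- setdiff(unique(out$subset), FREQ_SUBSETS)
  if (length(bad_sub) > 0) {
    stop("unknown subset label(s): ", paste(bad_sub, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(out$ac > out$an)) {
    stop("allele count (AC) exceeds allele number (AN) for some rows", call. = FALSE)
  }
  out
}

#' Merge reference sub-populations into composite groups
#'
#' Reference databases split some continental groups more finely than the
#' cohort labels (e.g. Finnish / non-Finnish / Ashkenazi European). A merging
#' recipe sums `ac` and `an` over the listed source populations within each
#' key and subset; `popmax_af` is carried as the maximum across sources.
#'
#' @param freq A frequency tibble from [read_frequencies()] (source
#'   population labels need not be in the continental set).
#' @param recipe Named list: output population -> character vector of source
#'   population labels, e.g. `list(eur = c("nfe", "fin", "asj"))`.
#' @return A frequency tibble with one row per key/merged population/subset.
#' @export
merge_populations <- function(freq, recipe) {
  purrr::imap_dfr(recipe, function(sources, target) {
    freq |>
      dplyr::filter(.data$population %in% sources) |>
      dplyr::group_by(.data$key, .data$gene, .data$subset) |>
      dplyr::summarise(
        ac = sum(.data$ac),
        an = sum(.data$an),
        popmax_af = if (all(is.na(.data$popmax_af))) NA_real_ else max(.data$popmax_af, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::mutate(population = target)
  }) |>
    dplyr::select("key", "gene", "population", "subset", "ac", "an", "popmax_af")
}

#' Attach reference allele frequencies to a P/LP variant set
#'
#' Joins a P/LP knowledge base to a population-frequency table on the
#' canonical variant key, for one population and subset. Records are joined
#' exactly as published; P/LP variants absent from the frequency table are
#' retained with `ac = 0`, `an = 0` and `absent = TRUE` so that
#' representation mismatches and genuinely unseen variants are visible rather
#' than silently dropped.
#'
#' @param plp_kb A knowledge-base tibble (rows assumed already restricted to
#'   `Path`/`LPath`, see [kb_plp()]).
#' @param freq_records A frequency tibble from [read_frequencies()].
#' @param population,subset The population and subset to select from
#'   `freq_records`.
#' @return A tibble with one row per P/LP key: `key`, `gene`,
#'   `classification`, `population`, `subset`, `ac`, `an`, `absent`.
#' @export
join_frequencies <- function(plp_kb, freq_records, population, subset) {
  sel <- freq_records |>
    dplyr::filter(.data$population == .env$population, .data$subset == .env$subset)
  if (anyDuplicated(sel$key) > 0) {
    dup <- unique(sel$key[duplicated(sel$key)])
    stop(
      "duplicate frequency rows for key(s) ", paste(dup, collapse = ", "),
      " in population '", population, "', subset '", subset, "'",
      call. = FALSE
    )
  }
  plp_kb |>
    dplyr::select("key", "gene", "classification") |>
    dplyr::left_join(
      dplyr::select(sel, "key", "ac", "an"),
      by = "key"
    ) |>
    dplyr::mutate(
      absent = is.na(.data$ac),
      ac = dplyr::coalesce(.data$ac, 0L),
      an = dplyr::coalesce(.data$an, 0L),
      population = .env$population,
      subset = .env$subset
    )
}
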