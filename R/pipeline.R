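#' Run the full burden-analysis pipeline
#'
#' Orchestrates classification, burden counting, statistics, external
#' frequency comparison and phenotype enrichment from a single configuration,
#' writing versioned TSV/JSON outputs and a run manifest (configuration
#' echo, input checksums, package version) so a run is reproducible from its
#' output directory alone.
#'
#' The configuration is a named list (or a YAML file holding one) with
#' elements:
#'
#' * `inputs`: paths `vcf`, `panel`, `vip`, `ancestry`, and optionally
#'   `clinvar`, `freq`, `ehr`, `survey`;
#' * `thresholds` (all optional): `gq` (20), `plof_af` (0.001), `alpha`
#'   (0.05), `ci_level` (0.95), `clinvar_cutoff_date` (`"2016-01-01"`);
#' * `toggles` (optional): `strand_aware_padding` (TRUE), `counting_mode`
#'   (`"participants"`), `reference_group` (`"eur"`), `freq_population`
#'   (`"eur"`), `freq_subset` (`"full"`);
#' * `hfe_key`: target variant key for an `hfe_special` panel gene;
#' * `enrichment` (optional): `condition_codes` (data frame or list with
#'   `code_system`, `code`), `survey_matches` (`question_id`, `answer`);
#' * `out_dir`: output directory.
#'
#' @param config A named list or path to a YAML file.
#' @return Invisibly, a list with every stage's result (`findings`,
#'   `burden`, `chisq`, `outlier_scan`, `rates_ci`, `comparison`,
#'   `enrichment`, `manifest`).
#' @export
run_burden_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  required <- c("vcf", "panel", "vip", "ancestry")
  missing_inputs <- setdiff(required, names(inputs))
  if (length(missing_inputs) > 0) {
    stop("config$inputs lacks: ", paste(missing_inputs, collapse = ", "),
      call. = FALSE
    )
  }
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      stop("input file not found (", nm, "): ", inputs[[nm]], call. = FALSE)
    }
  }
  th <- utils::modifyList(
    list(
      gq = 20, plof_af = 0.001, alpha = 0.05, ci_level = 0.95,
      clinvar_cutoff_date = "2016-01-01"
    ),
    config$thresholds %||% list()
  )
  tg <- utils::modifyList(
    list(
      strand_aware_padding = TRUE, counting_mode = "participants",
      reference_group = "eur", freq_population = "eur", freq_subset = "full"
    ),
    config$toggles %||% list()
  )
  out_dir <- config$out_dir %||% stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  message("[classify] reading inputs")
  panel <- read_panel(inputs$panel)
  kb <- read_vip(inputs$vip)
  if (!is.null(inputs$clinvar)) {
    cv <- read_clinvar(inputs$clinvar)
    kb_cv <- filter_clinvar_plp(cv, cutoff_date = th$clinvar_cutoff_date)
    kb <- dplyr::bind_rows(kb, dplyr::anti_join(kb_cv, kb, by = "key"))
  }
  calls <- read_cohort_vcf(inputs$vcf)
  ancestry <- readr::read_tsv(inputs$ancestry,
    show_col_types = FALSE,
    progress = FALSE
  )

  findings <- classify_cohort(
    calls, kb, panel,
    hfe_key = config$hfe_key,
    gq_threshold = th$gq, af_threshold = th$plof_af,
    strand_aware = tg$strand_aware_padding
  )
  message("[burden] counting findings")
  burden <- count_cohort(findings, ancestry,
    panel = panel,
    mode = tg$counting_mode
  )

  message("[stats] contingency and outlier tests")
  chisq <- tryCatch(
    chisq_independence(aggregate_for_chisq(burden)),
    error = function(e) {
      message("[stats] chi-square not computed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    }
  )
  scan <- gene_outlier_scan(burden,
    reference_group = tg$reference_group,
    alpha = th$alpha
  )
  rates_ci <- dplyr::bind_cols(
    burden$overall["group"],
    rate_with_ci(burden$overall$positives, burden$overall$n,
      level = th$ci_level
    )
  )

  comparison <- NULL
  if (!is.null(inputs$freq)) {
    message("[compare] external frequency comparison")
    freq <- read_frequencies(inputs$freq)
    plp <- kb_plp(kb)
    ref_rates <- dplyr::bind_rows(lapply(
      unique(freq$subset),
      function(s) {
        gene_level_rate(
          join_frequencies(plp, freq, tg$freq_population, s)
        )
      }
    ))
    cohort_rates <- cohort_gene_rates(findings, ancestry) |>
      dplyr::filter(.data$population == tg$freq_population)
    full_ref <- dplyr::filter(ref_rates, .data$subset == tg$freq_subset)
    corr <- rate_correlation(cohort_rates, full_ref)
    subset_report <- subset_resolution_report(cohort_rates, ref_rates)
    comparison <- list(
      reference_rates = ref_rates, cohort_rates = cohort_rates,
      correlation = corr, subset_report = subset_report
    )
  }

  enrichment <- NULL
  if (!is.null(inputs$ehr) && !is.null(config$enrichment)) {
    message("[enrich] phenotype-cohort enrichment")
    ehr <- readr::read_tsv(inputs$ehr, show_col_types = FALSE, progress = FALSE)
    survey <- if (!is.null(inputs$survey)) {
      readr::read_tsv(inputs$survey, show_col_types = FALSE, progress = FALSE)
    } else {
      tibble::tibble(
        participant_id = character(), question_id = character(),
        answer = character()
      )
    }
    crit <- phenotype_criteria(
      condition_codes = as_tibble_or_null(config$enrichment$condition_codes),
      survey_matches = as_tibble_or_null(config$enrichment$survey_matches)
    )
    cohort <- select_cohort(ehr, survey, crit,
      genotyped_ids = ancestry$participant_id
    )
    in_cohort <- cohort$participant_id[cohort$has_genotype]
    positives <- unique(findings$participant_id)
    enrichment <- enrichment_test(
      sum(in_cohort %in% positives), length(in_cohort),
      length(positives), nrow(ancestry)
    )
  }

  manifest <- list(
    package = "ancestryburden",
    version = as.character(utils::packageVersion("ancestryburden")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config[setdiff(names(config), "out_dir")],
    thresholds = th, toggles = tg,
    input_checksums = as.list(tools::md5sum(unlist(inputs)))
  )

  out <- function(f) file.path(out_dir, f)
  readr::write_tsv(findings, out("findings.tsv"), progress = FALSE)
  readr::write_tsv(tidy(burden), out("burden.tsv"), progress = FALSE)
  readr::write_tsv(scan, out("outlier_scan.tsv"), progress = FALSE)
  readr::write_tsv(rates_ci, out("rates_ci.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      chisq = chisq, overall = burden$overall,
      categories = burden$categories,
      enrichment = enrichment,
      correlation = if (!is.null(comparison)) {
        comparison$correlation[c("r", "n_genes", "flag")]
      }
    ),
    out("stats.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(comparison)) {
    readr::write_tsv(
      comparison$subset_report, out("subset_report.tsv"),
      progress = FALSE
    )
  }
  jsonlite::write_json(manifest, out("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    findings = findings, burden = burden, chisq = chisq,
    outlier_scan = scan, rates_ci = rates_ci, comparison = comparison,
    enrichment = enrichment, manifest = manifest
  ))
}

as_tibble_or_null <- function(x) {
  if (is.null(x)) {
    return(NULL)
  }
  tibble::as_tibble(lapply(x, unlist))
}
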