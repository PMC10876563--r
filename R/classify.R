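#' Genotype-quality filter
#'
#' A call passes when its phred-scaled genotype quality is *strictly* greater
#' than the threshold (the default reproduces the `GQ > 20` rule: GQ = 20
#' fails).
#'
#' @param gq Numeric vector of genotype qualities.
#' @param threshold Quality threshold (default 20).
#' @return Logical vector.
#' @export
passes_gq <- function(gq, threshold = 20) {
  gq > threshold
}

#' Predicted loss-of-function test
#'
#' A variant annotation qualifies as predicted loss of function (pLoF) when
#' all of the following hold:
#'
#' * the most severe consequence is one of `frameshift_variant`,
#'   `stop_gained`, `stop_lost`, `splice_acceptor_variant`,
#'   `splice_donor_variant`, `start_lost`;
#' * the LoF classifier confidence is `"high"`;
#' * the popmax allele frequency (maximum frequency across reference
#'   continental populations) is strictly below `af_threshold`, or missing —
#'   absence from the reference database is taken to imply rarity.
#'
#' @param consequence Character vector of SO consequence terms.
#' @param lof_confidence Character vector: `"high"`, `"low"` or `"missing"`.
#' @param popmax_af Numeric vector of popmax allele frequencies (`NA` =
#'   absent from the reference database).
#' @param af_threshold Rarity threshold (default 0.001, strict `<`).
#' @return Logical vector.
#' @examples
#' is_plof("stop_gained", "high", 0.0005) # TRUE
#' is_plof("stop_gained", "high", 0.001) # FALSE: threshold is strict
#' @export
is_plof <- function(consequence, lof_confidence, popmax_af, af_threshold = 0.001) {
  consequence %in% LOF_CONSEQUENCES &
    lof_confidence == "high" &
    (is.na(popmax_af) | popmax_af < af_threshold)
}

#' Assign calls to padded panel regions
#'
#' Subsets a call table to the padded gene regions of the panel and attaches
#' the per-gene metadata (`gene`, `strand`, `inheritance`, `lof_mechanism`).
#' Calls outside every padded region are dropped; their count is reported via
#' the `n_outside` attribute and a message.
#'
#' @param calls A call tibble ([read_cohort_vcf()] output).
#' @param padded_panel A padded panel tibble ([pad_region()] output).
#' @return The in-panel calls with panel columns attached.
#' @export
subset_panel_calls <- function(calls, padded_panel) {
  joined <- dplyr::inner_join(
    calls, padded_panel,
    by = dplyr::join_by(chrom, dplyr::between(pos, start, end))
  ) |>
    dplyr::select(-"start", -"end")
  n_outside <- nrow(calls) - nrow(dplyr::distinct(
    joined, .data$participant_id, .data$key
  ))
  if (n_outside > 0) {
    message(n_outside, " call(s) outside the padded panel were dropped")
  }
  attr(joined, "n_outside") <- n_outside
  joined
}

#' Identify qualifying findings per participant and gene
#'
#' Applies the zygosity-aware matching rules to GQ-passing, panel-subsetted
#' calls and returns one finding per participant x gene x variant:
#'
#' * **known_plp** — the call's key is in the P/LP knowledge base and the
#'   gene's inheritance rule admits it: any zygosity for dominant-acting
#'   genes; homozygous only for the recessive genes; for the `hfe_special`
#'   gene only the configured target variant (hereditary-hemochromatosis
#'   C282Y, `NM_000410.4:c.845G>A`, rs1800562) in the homozygous state.
#' * **plof_known_overlap** — a pLoF call (see [is_plof()]) in a gene with a
#'   loss-of-function disease mechanism whose key is also in the P/LP
#'   knowledge base, but which did not already qualify as `known_plp`.
#' * **plof_novel** — a pLoF call in a LoF-mechanism gene absent from the
#'   knowledge base.
#'
#' Each (participant, gene, key) yields at most one finding, with precedence
#' `known_plp` > `plof_known_overlap` > `plof_novel`. Compound
#' heterozygotes in recessive genes do not qualify (no phasing is
#' attempted). The `plof` column flags findings whose variant is pLoF
#' regardless of category, supporting overlap-style reporting.
#'
#' @param calls Panel-subsetted calls ([subset_panel_calls()] output). All
#'   calls must pass the GQ filter and lie in a padded panel region; violations
#'   are an error, since silent refiltering here would mask caller bugs.
#' @param kb A knowledge-base tibble; only its `Path`/`LPath` rows are used.
#' @param hfe_key Canonical key of the target variant for any `hfe_special`
#'   gene. Required if the panel contains one.
#' @param gq_threshold GQ threshold the calls are expected to satisfy.
#' @param af_threshold pLoF rarity threshold passed to [is_plof()].
#' @return A tibble: `participant_id`, `gene`, `key`, `zygosity`,
#'   `category`, `plof`.
#' @export
qualifying_findings <- function(calls, kb, hfe_key = NULL,
                                gq_threshold = 20, af_threshold = 0.001) {
  required <- c(
    "participant_id", "key", "gene", "zygosity", "gq",
    "consequence", "lof_confidence", "popmax_af", "inheritance", "lof_mechanism"
  )
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0) {
    stop(
      "calls lack column(s) ", paste(missing_cols, collapse = ", "),
      "; run subset_panel_calls() first",
      call. = FALSE
    )
  }
  if (any(!passes_gq(calls$gq, gq_threshold))) {
    stop("calls contain GQ <= ", gq_threshold,
      "; filter with passes_gq() before classifying",
      call. = FALSE
    )
  }
  if (any(calls$inheritance == "hfe_special") && is.null(hfe_key)) {
    stop("panel contains an hfe_special gene but `hfe_key` is not set",
      call. = FALSE
    )
  }
  plp_keys <- kb_plp(kb)$key

  scored <- calls |>
    dplyr::mutate(
      in_kb = .data$key %in% plp_keys,
      plof = is_plof(
        .data$consequence, .data$lof_confidence, .data$popmax_af,
        af_threshold
      ),
      known_plp = .data$in_kb & dplyr::case_when(
        .data$inheritance == "dominant_like" ~
          .data$zygosity %in% c("het", "hom_alt"),
        .data$inheritance == "recessive_homozygous_only" ~
          .data$zygosity == "hom_alt",
        .data$inheritance == "hfe_special" ~
          .data$zygosity == "hom_alt" & .data$key == (hfe_key %||% ""),
        TRUE ~ FALSE
      ),
      plof_hit = .data$plof & .data$lof_mechanism,
      category = dplyr::case_when(
        .data$known_plp ~ "known_plp",
        .data$plof_hit & .data$in_kb ~ "plof_known_overlap",
        .data$plof_hit ~ "plof_novel",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$category))

  scored |>
    dplyr::mutate(category = factor(
      .data$category,
      levels = c("known_plp", "plof_known_overlap", "plof_novel")
    )) |>
    dplyr::arrange(
      .data$participant_id, .data$gene, .data$key, .data$category
    ) |>
    dplyr::distinct(
      .data$participant_id, .data$gene, .data$key,
      .keep_all = TRUE
    ) |>
    dplyr::mutate(category = as.character(.data$category)) |>
    dplyr::select(
      "participant_id", "gene", "key", "zygosity", "category", "plof"
    )
}

#' Classify a cohort end to end
#'
#' Convenience wrapper: pads the panel, subsets calls to padded regions,
#' applies the GQ filter, and derives qualifying findings.
#'
#' @param calls Raw call tibble ([read_cohort_vcf()] output).
#' @param kb Knowledge-base tibble.
#' @param panel Panel tibble ([read_panel()] output, unpadded).
#' @param hfe_key Target key for the `hfe_special` gene (see
#'   [qualifying_findings()]).
#' @param gq_threshold,af_threshold Filtering thresholds.
#' @param upstream_bp,downstream_bp,strand_aware Padding parameters
#'   ([pad_region()]).
#' @return A findings tibble (see [qualifying_findings()]).
#' @export
classify_cohort <- function(calls, kb, panel, hfe_key = NULL,
                            gq_threshold = 20, af_threshold = 0.001,
                            upstream_bp = 2000, downstream_bp = 1000,
                            strand_aware = TRUE) {
  padded <- pad_region(panel,
    upstream_bp = upstream_bp,
    downstream_bp = downstream_bp, strand_aware = strand_aware
  )
  in_panel <- subset_panel_calls(calls, padded)
  kept <- dplyr::filter(in_panel, passes_gq(.data$gq, gq_threshold))
  qualifying_findings(kept, kb,
    hfe_key = hfe_key,
    gq_threshold = gq_threshold, af_threshold = af_threshold
  )
}
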