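## Independent RNG streams per simulation stage, derived from one root seed.
## Stage k always gets the same stream regardless of which stages run, so
## adding or reordering stages never perturbs the others.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483629)
}

#' Default per-gene, per-ancestry planted carrier rates
#'
#' Planted probabilities (per participant) of a qualifying known-P/LP
#' finding and of a novel qualifying pLoF finding, per gene and ancestry
#' group. The defaults reproduce the burden structure of a large
#' diverse-cohort study: known-P/LP totals of ~2.13% (eur), ~1.52% (afr),
#' highest overall positive rate in the European group (~2.26%) and lowest
#' in the Latino/Admixed American group (~1.32%); gene-level afr-vs-eur
#' divergences in APOB (lower), PKP2 and PALB2 (higher); an HFE homozygote
#' rate of ~0.41% in eur versus ~0.02% in afr; and novel-pLoF rates highest
#' in the South Asian (0.85%) and East Asian (0.62%) groups.
#'
#' @return A tibble: `gene`, `ancestry`, `plp_rate`, `plof_rate` (fractions).
#' @export
default_gene_rates <- function() {
  genes <- c(
    "BRCA2", "LDLR", "APOB", "PKP2", "PALB2", "MYH7",
    "MUTYH", "ATP7B", "KCNQ1", "HFE"
  )
  # rows: genes (order above); cols: eur, afr, amr, eas, sas, mid, oth; in %
  plp <- matrix(c(
    0.55, 0.40, 0.25, 0.20, 0.20, 0.25, 0.55,
    0.49, 0.45, 0.30, 0.25, 0.30, 0.35, 0.40,
    0.11, 0.02, 0.05, 0.03, 0.03, 0.05, 0.08,
    0.04, 0.14, 0.05, 0.03, 0.03, 0.04, 0.06,
    0.06, 0.14, 0.05, 0.04, 0.04, 0.05, 0.08,
    0.40, 0.32, 0.20, 0.15, 0.15, 0.20, 0.39,
    0.03, 0.01, 0.01, 0.01, 0.01, 0.01, 0.02,
    0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.02,
    0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.02,
    0.41, 0.02, 0.24, 0.02, 0.02, 0.10, 0.20
  ), nrow = 10, byrow = TRUE)
  # novel-pLoF totals per ancestry (%), split across the LoF-mechanism genes
  plof_totals <- c(
    eur = 0.13, afr = 0.10, amr = 0.15, eas = 0.62,
    sas = 0.85, mid = 0.30, oth = 0.19
  )
  lof_genes <- genes[1:6]
  groups <- c("eur", "afr", "amr", "eas", "sas", "mid", "oth")
  tidyr::expand_grid(gene = genes, ancestry = groups) |>
    dplyr::mutate(
      plp_rate = plp[cbind(
        match(.data$gene, genes), match(.data$ancestry, groups)
      )] / 100,
      plof_rate = ifelse(
        .data$gene %in% lof_genes,
        plof_totals[.data$ancestry] / length(lof_genes) / 100,
        0
      )
    )
}

default_sim_panel <- function() {
  genes <- c(
    "BRCA2", "LDLR", "APOB", "PKP2", "PALB2", "MYH7",
    "MUTYH", "ATP7B", "KCNQ1", "HFE"
  )
  tibble::tibble(
    gene = genes,
    chrom = paste0("chr", seq_along(genes)),
    start = 100000L,
    end = 150000L,
    strand = rep(c("+", "-"), 5),
    inheritance = c(
      rep("dominant_like", 6),
      rep("recessive_homozygous_only", 3),
      "hfe_special"
    ),
    lof_mechanism = c(rep(TRUE, 6), rep(FALSE, 4))
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-cohort generator. The defaults
#' are the study conditions of a large diverse whole-genome cohort: 98,590
#' participants with ancestry composition 50.4% eur, 23.2% afr, 16.1% amr,
#' 2.1% eas, 1.0% sas, 0.2% mid, 7.0% oth (exact counts 49,668 / 22,897 /
#' 15,893 / 2,113 / 940 / 193 / 6,886), the planted carrier rates of
#' [default_gene_rates()], and 5% of genotypes falling at or below the
#' GQ = 20 threshold. Tests and examples pass a smaller `n_participants`
#' explicitly.
#'
#' @param seed Root seed; fully determines every output.
#' @param n_participants Cohort size.
#' @param ancestry_proportions Named numeric vector over the seven ancestry
#'   groups, summing to 1 (tolerance 1e-9).
#' @param panel Panel tibble (genes, toy contigs/coordinates, strand,
#'   inheritance, LoF mechanism).
#' @param rates Planted rate tibble (see [default_gene_rates()]).
#' @param gq_below_frac Fraction of calls drawn with GQ <= `gq_threshold`.
#' @param gq_threshold GQ threshold the pipeline will apply.
#' @param overlap_frac Fraction of each gene's P/LP knowledge-base variants
#'   that carry a high-confidence LoF consequence (so known-P/LP and pLoF
#'   annotation overlap, as they do for frameshift pathogenic variants).
#' @param decoy Named list of nuisance rates: `vus_rate`, `benign_rate`
#'   (carriers of non-P/LP knowledge-base variants), `lowconf_rate`
#'   (low-confidence LoF calls), `common_lof_rate` (LoF consequence but
#'   popmax frequency above the rarity threshold), `outside_rate` (calls
#'   beyond the padded panel), `rec_het_rate` (heterozygous calls in
#'   recessive genes), `hfe_het_rate` (heterozygous carriers of the HFE
#'   target variant), `hfe_nontarget_hom_rate` (homozygous carriers of a
#'   non-target HFE P/LP variant). None of these should ever yield a
#'   qualifying finding.
#' @param clinvar_noise Named list of proportions assigning each P/LP
#'   variant's ClinVar record to a review-status/date stratum:
#'   `two_star_recent`, `two_star_old`, `two_star_missing_date`,
#'   `one_star`, `conflicting`, `three_star`, `four_star` (must sum to 1);
#'   plus `grch37_dup_frac`, the fraction of records duplicated as GRCh37
#'   rows.
#' @param subset_effects Tibble (`gene`, `subset`, `factor`) inflating
#'   reference allele counts in specific database subsets, to emulate
#'   disease-ascertained samples present in the full release but absent
#'   from e.g. a non-cancer subset.
#' @param phenotype Named list linking carrier status to a phenotype:
#'   `linked_genes`, relative risk `rr`, `base_rate`, the condition
#'   `codes` (SNOMED), survey `question_id` and `answer`.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_participants = 98590L,
                       ancestry_proportions = c(
                         eur = 49668, afr = 22897, amr = 15893, eas = 2113,
                         sas = 940, mid = 193, oth = 6886
                       ) / 98590,
                       panel = default_sim_panel(),
                       rates = default_gene_rates(),
                       gq_below_frac = 0.05,
                       gq_threshold = 20,
                       overlap_frac = 0.22,
                       decoy = list(),
                       clinvar_noise = list(),
                       subset_effects = NULL,
                       phenotype = list()) {
  decoy_defaults <- list(
    vus_rate = 0.003, benign_rate = 0.002, lowconf_rate = 0.002,
    common_lof_rate = 0.003, outside_rate = 0.001, rec_het_rate = 0.004,
    hfe_het_rate = 0.06, hfe_nontarget_hom_rate = 0.0003
  )
  decoy <- utils::modifyList(decoy_defaults, decoy)
  cv_defaults <- list(
    two_star_recent = 0.40, two_star_old = 0.15, two_star_missing_date = 0.05,
    one_star = 0.15, conflicting = 0.10, three_star = 0.10, four_star = 0.05,
    grch37_dup_frac = 0.2
  )
  clinvar_noise <- utils::modifyList(cv_defaults, clinvar_noise)
  ph_defaults <- list(
    linked_genes = c("BRCA2", "PALB2"), rr = 4.6, base_rate = 0.017,
    codes = c("254837009", "372064008"),
    question_id = "cancer_history", answer = "breast cancer"
  )
  phenotype <- utils::modifyList(ph_defaults, phenotype)
  if (is.null(subset_effects)) {
    subset_effects <- tibble::tibble(
      gene = c("BRCA2", "LDLR", "LDLR"),
      subset = c("full", "full", "non_cancer"),
      factor = c(1.7, 1.6, 1.6)
    )
  }

  if (abs(sum(ancestry_proportions) - 1) > 1e-9) {
    stop("ancestry proportions must sum to 1", call. = FALSE)
  }
  all_rates <- c(
    rates$plp_rate, rates$plof_rate, gq_below_frac,
    unlist(decoy), phenotype$base_rate
  )
  if (any(all_rates < 0 | all_rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  strata <- unlist(clinvar_noise[c(
    "two_star_recent", "two_star_old", "two_star_missing_date",
    "one_star", "conflicting", "three_star", "four_star"
  )])
  if (abs(sum(strata) - 1) > 1e-9) {
    stop("clinvar_noise strata must sum to 1", call. = FALSE)
  }
  validate_panel(panel)
  structure(
    list(
      seed = as.integer(seed), n_participants = as.integer(n_participants),
      ancestry_proportions = ancestry_proportions, panel = panel,
      rates = rates, gq_below_frac = gq_below_frac,
      gq_threshold = gq_threshold, overlap_frac = overlap_frac,
      decoy = decoy, clinvar_noise = clinvar_noise,
      subset_effects = subset_effects, phenotype = phenotype
    ),
    class = "sim_config"
  )
}

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample(1:3, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1 + shift) %% 4 + 1]
  list(ref = ref, alt = alt)
}

## Draw n distinct variant records for one gene, spread over coding,
## near-gene padding (<= 900 bp either side, inside the padded region under
## both strand conventions) and far-outside positions.
draw_gene_variants <- function(gene_row, n_coding, n_padding, n_outside) {
  n <- n_coding + n_padding + n_outside
  pos <- c(
    sample(seq(gene_row$start, gene_row$end), n_coding),
    sample(c(
      seq(gene_row$start - 900, gene_row$start - 1),
      seq(gene_row$end + 1, gene_row$end + 900)
    ), n_padding),
    sample(seq(gene_row$end + 5000, gene_row$end + 9000), n_outside)
  )
  al <- random_snv_alleles(n)
  tibble::tibble(
    gene = gene_row$gene, chrom = gene_row$chrom, pos = as.integer(pos),
    ref = al$ref, alt = al$alt,
    placement = rep(
      c("coding", "padding", "outside"),
      c(n_coding, n_padding, n_outside)
    )
  )
}

#' Simulate the variant knowledge sources
#'
#' Generates, from the planted panel, a master variant table plus the three
#' knowledge-source files the pipeline consumes: a curated P/LP database
#' (with VUS/benign/risk decoys), a ClinVar-style record set spanning all
#' star levels, evaluation dates on both sides of the filter cutoff, the six
#' P/LP significance strings and conflicting-interpretation decoys (plus
#' GRCh37 duplicate rows), and a per-population, per-subset allele-frequency
#' table with planted inflation of designated gene/subset combinations.
#'
#' @param config A [sim_config()] object.
#' @return A list: `variants` (master table with roles and annotations),
#'   `vip` (knowledge-base tibble, [read_vip()] schema), `clinvar`
#'   ([read_clinvar()] schema), `freq` ([read_frequencies()] schema),
#'   `hfe_key` (the target key of the `hfe_special` gene, if any).
#' @export
simulate_knowledgebase <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 1L))
  panel <- config$panel

  pools <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    g <- panel[i, ]
    # 6 coding P/LP + 2 padding P/LP, 6 novel LoF, 3 LoF decoys,
    # 8 classified decoys, 2 outside-panel
    v <- draw_gene_variants(g, n_coding = 23, n_padding = 2, n_outside = 2)
    role <- c(
      rep("plp", 6), rep("plof_novel", 6), rep("lowconf_lof", 2),
      "common_lof", rep("vus", 4), rep("benign", 2), "lbenign", "risk",
      rep("plp", 2), rep("outside", 2)
    )
    v$role <- role
    pools[[i]] <- v
  }
  variants <- dplyr::bind_rows(pools)

  n_var <- nrow(variants)
  variants$classification <- dplyr::case_when(
    variants$role == "plp" ~ NA_character_, # assigned below
    variants$role == "vus" ~ "VUS",
    variants$role == "benign" ~ "Benign",
    variants$role == "lbenign" ~ "LBenign",
    variants$role == "risk" ~ "Risk",
    TRUE ~ NA_character_
  )
  is_plp <- variants$role == "plp"
  variants$classification[is_plp] <- sample(
    c("Path", "LPath"), sum(is_plp),
    replace = TRUE, prob = c(0.65, 0.35)
  )

  # annotations: P/LP variants overlap the LoF set at overlap_frac; novel
  # LoF variants are high-confidence and rare; decoys break exactly one rule
  lof_terms <- LOF_CONSEQUENCES
  variants$consequence <- "missense_variant"
  variants$lof_confidence <- "missing"
  variants$popmax_af <- NA_real_

  plp_lof <- is_plp & stats::runif(n_var) < config$overlap_frac
  variants$consequence[plp_lof] <-
    sample(c("frameshift_variant", "stop_gained"), sum(plp_lof), replace = TRUE)
  variants$lof_confidence[plp_lof] <- "high"
  variants$popmax_af[plp_lof] <-
    ifelse(stats::runif(sum(plp_lof)) < 0.5, NA_real_, 1e-5)

  novel <- variants$role == "plof_novel"
  variants$consequence[novel] <- sample(lof_terms, sum(novel), replace = TRUE)
  variants$lof_confidence[novel] <- "high"
  variants$popmax_af[novel] <-
    ifelse(stats::runif(sum(novel)) < 0.5, NA_real_, 5e-4)

  lowconf <- variants$role == "lowconf_lof"
  variants$consequence[lowconf] <- sample(lof_terms, sum(lowconf), replace = TRUE)
  variants$lof_confidence[lowconf] <- "low"
  variants$popmax_af[lowconf] <- 1e-4

  common <- variants$role == "common_lof"
  variants$consequence[common] <- "stop_gained"
  variants$lof_confidence[common] <- "high"
  variants$popmax_af[common] <- 0.005 # fails the < 0.001 rarity rule

  outside <- variants$role == "outside"
  variants$consequence[outside] <- "stop_gained"
  variants$lof_confidence[outside] <- "high"
  variants$popmax_af[outside] <- NA_real_

  variants$key <- variant_key(
    variants$chrom, variants$pos, variants$ref, variants$alt
  )

  # the HFE-style gene's target variant: its first coding P/LP variant
  hfe_key <- NULL
  hfe_gene <- panel$gene[panel$inheritance == "hfe_special"]
  if (length(hfe_gene) > 0) {
    hfe_key <- variants$key[variants$gene == hfe_gene[1] &
      is_plp & variants$placement == "coding"][1]
  }

  classified <- variants[!is.na(variants$classification), ]
  vip <- tibble::tibble(
    key = classified$key, gene = classified$gene,
    classification = classified$classification,
    hgvs_c = NA_character_, source = "synthetic"
  )

  clinvar <- simulate_clinvar_records(variants, config)
  freq <- simulate_freq_table(variants, config)

  list(
    variants = variants, vip = vip, clinvar = clinvar, freq = freq,
    hfe_key = hfe_key
  )
}

simulate_clinvar_records <- function(variants, config) {
  set.seed(stream_seed(config$seed, 2L))
  noise <- config$clinvar_noise
  plp <- variants[variants$role == "plp", ]
  strata <- c(
    "two_star_recent", "two_star_old", "two_star_missing_date",
    "one_star", "conflicting", "three_star", "four_star"
  )
  assign <- sample(strata, nrow(plp),
    replace = TRUE,
    prob = unlist(noise[strata])
  )
  recent <- function(n) {
    as.Date("2016-01-01") + sample.int(2000, n, replace = TRUE)
  }
  old <- function(n) as.Date("2008-01-01") + sample.int(2800, n, replace = TRUE)
  n <- nrow(plp)
  status <- character(n)
  sig <- sample(CLINVAR_PLP_SIGNIFICANCE, n, replace = TRUE)
  date <- rep(as.Date(NA), n)
  ms <- "criteria provided, multiple submitters, no conflicts"
  status[assign == "two_star_recent"] <- ms
  date[assign == "two_star_recent"] <- recent(sum(assign == "two_star_recent"))
  status[assign == "two_star_old"] <- ms
  date[assign == "two_star_old"] <- old(sum(assign == "two_star_old"))
  status[assign == "two_star_missing_date"] <- ms
  status[assign == "one_star"] <- "criteria provided, single submitter"
  date[assign == "one_star"] <- recent(sum(assign == "one_star"))
  status[assign == "conflicting"] <- "criteria provided, conflicting interpretations"
  sig[assign == "conflicting"] <- "Conflicting interpretations of pathogenicity"
  date[assign == "conflicting"] <- recent(sum(assign == "conflicting"))
  status[assign == "three_star"] <- "reviewed by expert panel"
  date[assign == "three_star"] <- old(sum(assign == "three_star"))
  status[assign == "four_star"] <- "practice guideline"
  date[assign == "four_star"] <- old(sum(assign == "four_star"))

  records <- tibble::tibble(
    key = plp$key, assembly = "GRCh38", gene = plp$gene,
    clinical_significance = sig, review_status = status,
    stars = clinvar_stars(status), last_evaluated = date,
    stratum = assign
  )
  # VUS decoys and GRCh37 duplicates
  vus <- variants[variants$role == "vus", ]
  vus_rec <- tibble::tibble(
    key = vus$key, assembly = "GRCh38", gene = vus$gene,
    clinical_significance = "Uncertain significance",
    review_status = ms, stars = 2L, last_evaluated = recent(nrow(vus)),
    stratum = "vus"
  )
  dup <- records[stats::runif(n) < noise$grch37_dup_frac, ]
  dup$assembly <- "GRCh37"
  dplyr::bind_rows(records, vus_rec, dup)
}

simulate_freq_table <- function(variants, config) {
  set.seed(stream_seed(config$seed, 3L))
  base_an <- c(
    eur = 129000, afr = 41000, amr = 35000, eas = 19000,
    sas = 30000, mid = 3000, oth = 1000
  )
  subset_scale <- c(full = 1, non_cancer = 0.9, non_topmed = 0.8)
  tracked <- variants[variants$role %in% c("plp", "plof_novel"), ]
  rates <- config$rates
  grid <- tidyr::expand_grid(
    idx = seq_len(nrow(tracked)),
    population = names(base_an),
    subset = names(subset_scale)
  )
  v <- tracked[grid$idx, ]
  rate_lu <- rates |>
    dplyr::mutate(
      af = ifelse(.data$plp_rate > 0, .data$plp_rate, .data$plof_rate) / 2 / 8
    )
  af <- rate_lu$af[match(
    paste(v$gene, grid$population),
    paste(rate_lu$gene, rate_lu$ancestry)
  )]
  af[is.na(af)] <- 1e-5
  an <- as.integer(round(base_an[grid$population] *
    subset_scale[grid$subset] * stats::runif(nrow(grid), 0.95, 1)))
  infl <- config$subset_effects
  factor <- infl$factor[match(
    paste(v$gene, grid$subset),
    paste(infl$gene, infl$subset)
  )]
  factor[is.na(factor)] <- 1
  ac <- as.integer(pmin(an, round(af * factor * an)))
  tibble::tibble(
    key = v$key, gene = v$gene,
    population = grid$population, subset = grid$subset,
    ac = ac, an = an,
    popmax_af = v$popmax_af
  )
}

draw_gq <- function(n, below_frac) {
  below <- stats::runif(n) < below_frac
  ifelse(below,
    sample(0:20, n, replace = TRUE),
    sample(21:99, n, replace = TRUE)
  )
}

#' Simulate a genotyped cohort with planted findings
#'
#' Draws a cohort of participants (ancestry from the configured
#' proportions), plants qualifying carriers per gene at the configured
#' per-ancestry rates — with zygosity respecting each gene's inheritance
#' mode, so every planted carrier genuinely qualifies — adds the decoy call
#' classes that must *not* qualify, samples genotype qualities, links a
#' phenotype to carriers of the configured genes, and records every planted
#' qualifying finding in a truth table.
#'
#' @param config A [sim_config()] object.
#' @param kb Optionally a pre-built [simulate_knowledgebase()] result (it is
#'   generated from `config` otherwise).
#' @return A list of class `burden_sim`: `config`, `panel`, `kb` elements
#'   (`variants`, `vip`, `clinvar`, `freq`, `hfe_key`), `ancestry`
#'   (tibble `participant_id`, `ancestry`), `calls` (the
#'   [read_cohort_vcf()] schema), `truth` (planted qualifying findings with
#'   `gq` and `gq_pass`), `ehr`, `survey`, `samples`.
#' @export
simulate_cohort <- function(config, kb = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(kb)) kb <- simulate_knowledgebase(config)
  variants <- kb$variants
  panel <- config$panel

  set.seed(stream_seed(config$seed, 4L))
  n <- config$n_participants
  samples <- sprintf("P%07d", seq_len(n))
  ancestry <- tibble::tibble(
    participant_id = samples,
    ancestry = sample(
      names(config$ancestry_proportions), n,
      replace = TRUE, prob = config$ancestry_proportions
    )
  )

  set.seed(stream_seed(config$seed, 5L))
  call_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(panel))) {
    g <- panel[i, ]
    gene_vars <- variants[variants$gene == g$gene, ]
    plp_pool <- gene_vars[gene_vars$role == "plp", ]
    qualifying_pool <- if (g$inheritance == "hfe_special") {
      plp_pool[plp_pool$key == kb$hfe_key, ]
    } else {
      plp_pool
    }
    novel_pool <- gene_vars[gene_vars$role == "plof_novel", ]
    gene_rates <- config$rates[config$rates$gene == g$gene, ]

    for (a in unique(ancestry$ancestry)) {
      ids <- ancestry$participant_id[ancestry$ancestry == a]
      r <- gene_rates[gene_rates$ancestry == a, ]
      if (nrow(r) == 0) next

      # planted known-P/LP carriers
      carriers <- ids[stats::runif(length(ids)) < r$plp_rate]
      if (length(carriers) > 0 && nrow(qualifying_pool) > 0) {
        vi <- sample.int(nrow(qualifying_pool), length(carriers), replace = TRUE)
        zyg <- switch(g$inheritance,
          dominant_like = ifelse(
            stats::runif(length(carriers)) < 0.02, "hom_alt", "het"
          ),
          "hom_alt"
        )
        gq <- draw_gq(length(carriers), config$gq_below_frac)
        call_rows[[length(call_rows) + 1]] <- tibble::tibble(
          participant_id = carriers,
          key = qualifying_pool$key[vi],
          zygosity = zyg, gq = gq, planted = TRUE
        )
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          participant_id = carriers, gene = g$gene,
          key = qualifying_pool$key[vi], zygosity = zyg,
          category = "known_plp",
          plof = is_plof(
            qualifying_pool$consequence[vi],
            qualifying_pool$lof_confidence[vi],
            qualifying_pool$popmax_af[vi]
          ),
          gq = gq, gq_pass = passes_gq(gq, config$gq_threshold)
        )
      }

      # planted novel pLoF carriers
      if (g$lof_mechanism && nrow(novel_pool) > 0) {
        lcar <- ids[stats::runif(length(ids)) < r$plof_rate]
        if (length(lcar) > 0) {
          vi <- sample.int(nrow(novel_pool), length(lcar), replace = TRUE)
          zyg <- ifelse(stats::runif(length(lcar)) < 0.01, "hom_alt", "het")
          gq <- draw_gq(length(lcar), config$gq_below_frac)
          call_rows[[length(call_rows) + 1]] <- tibble::tibble(
            participant_id = lcar, key = novel_pool$key[vi],
            zygosity = zyg, gq = gq, planted = TRUE
          )
          truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
            participant_id = lcar, gene = g$gene,
            key = novel_pool$key[vi], zygosity = zyg,
            category = "plof_novel", plof = TRUE,
            gq = gq, gq_pass = passes_gq(gq, config$gq_threshold)
          )
        }
      }
    }

    # decoy call classes (ancestry-independent rates; never qualifying)
    d <- config$decoy
    decoy_spec <- list(
      list(pool = gene_vars[gene_vars$role == "vus", ], rate = d$vus_rate, zyg = "het"),
      list(
        pool = gene_vars[gene_vars$role %in% c("benign", "lbenign", "risk"), ],
        rate = d$benign_rate, zyg = "het"
      ),
      list(pool = gene_vars[gene_vars$role == "lowconf_lof", ], rate = d$lowconf_rate, zyg = "het"),
      list(pool = gene_vars[gene_vars$role == "common_lof", ], rate = d$common_lof_rate, zyg = "het"),
      list(pool = gene_vars[gene_vars$role == "outside", ], rate = d$outside_rate, zyg = "het")
    )
    if (g$inheritance == "recessive_homozygous_only") {
      decoy_spec <- c(decoy_spec, list(
        list(pool = plp_pool, rate = d$rec_het_rate, zyg = "het")
      ))
    }
    if (g$inheritance == "hfe_special") {
      decoy_spec <- c(decoy_spec, list(
        list(pool = qualifying_pool, rate = d$hfe_het_rate, zyg = "het"),
        list(
          pool = plp_pool[plp_pool$key != kb$hfe_key, ],
          rate = d$hfe_nontarget_hom_rate, zyg = "hom_alt"
        )
      ))
    }
    for (spec in decoy_spec) {
      if (nrow(spec$pool) == 0 || spec$rate <= 0) next
      hit <- samples[stats::runif(n) < spec$rate]
      if (length(hit) == 0) next
      vi <- sample.int(nrow(spec$pool), length(hit), replace = TRUE)
      call_rows[[length(call_rows) + 1]] <- tibble::tibble(
        participant_id = hit, key = spec$pool$key[vi],
        zygosity = spec$zyg, gq = draw_gq(length(hit), config$gq_below_frac),
        planted = FALSE
      )
    }
  }

  empty_calls <- tibble::tibble(
    participant_id = character(), key = character(), zygosity = character(),
    gq = integer(), planted = logical()
  )
  empty_truth <- tibble::tibble(
    participant_id = character(), gene = character(), key = character(),
    zygosity = character(), category = character(), plof = logical(),
    gq = integer(), gq_pass = logical()
  )
  calls <- dplyr::bind_rows(empty_calls, call_rows) |>
    dplyr::arrange(dplyr::desc(.data$planted)) |>
    dplyr::distinct(.data$participant_id, .data$key, .keep_all = TRUE) |>
    dplyr::select(-"planted")
  truth <- dplyr::bind_rows(empty_truth, truth_rows) |>
    dplyr::distinct(.data$participant_id, .data$gene, .data$key, .keep_all = TRUE) |>
    dplyr::arrange(.data$participant_id, .data$gene, .data$key)

  ann <- variants[match(calls$key, variants$key), ]
  calls <- tibble::tibble(
    participant_id = calls$participant_id, key = calls$key,
    chrom = ann$chrom, pos = ann$pos, ref = ann$ref, alt = ann$alt,
    zygosity = calls$zygosity, gq = as.numeric(calls$gq),
    consequence = ann$consequence, lof_confidence = ann$lof_confidence,
    popmax_af = ann$popmax_af
  ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$participant_id)

  pheno <- simulate_phenotype(config, samples, truth)

  structure(
    list(
      config = config, panel = panel, kb = kb, ancestry = ancestry,
      calls = calls, truth = truth, ehr = pheno$ehr, survey = pheno$survey,
      samples = samples
    ),
    class = "burden_sim"
  )
}

simulate_phenotype <- function(config, samples, truth) {
  set.seed(stream_seed(config$seed, 6L))
  ph <- config$phenotype
  carriers <- unique(truth$participant_id[
    truth$gene %in% ph$linked_genes & truth$category == "known_plp"
  ])
  p <- ifelse(samples %in% carriers, pmin(1, ph$base_rate * ph$rr), ph$base_rate)
  affected <- samples[stats::runif(length(samples)) < p]
  route <- sample(c("both", "code", "survey"), length(affected),
    replace = TRUE, prob = c(0.4, 0.3, 0.3)
  )
  with_code <- affected[route %in% c("both", "code")]
  with_survey <- affected[route %in% c("both", "survey")]
  ehr <- tibble::tibble(
    participant_id = with_code,
    code_system = "SNOMED",
    code = sample(ph$codes, length(with_code), replace = TRUE)
  )
  # unrelated condition codes as background noise
  noise_ids <- samples[stats::runif(length(samples)) < 0.05]
  ehr <- dplyr::bind_rows(ehr, tibble::tibble(
    participant_id = noise_ids, code_system = "SNOMED", code = "38341003"
  ))
  survey <- tibble::tibble(
    participant_id = with_survey,
    question_id = ph$question_id,
    answer = ph$answer
  )
  noise_ids2 <- samples[stats::runif(length(samples)) < 0.05]
  survey <- dplyr::bind_rows(survey, tibble::tibble(
    participant_id = noise_ids2, question_id = ph$question_id,
    answer = "skin cancer"
  ))
  list(
    ehr = dplyr::arrange(ehr, .data$participant_id),
    survey = dplyr::arrange(survey, .data$participant_id)
  )
}

#' Write a simulated cohort to disk
#'
#' Serializes every input file the pipeline consumes: `cohort.vcf`,
#' `panel.tsv` (BED-like, 0-based half-open starts), `vip.tsv`,
#' `clinvar.tsv`, `freq.tsv`, `ancestry.tsv`, `ehr.tsv`, `survey.tsv` and
#' `truth.tsv`. With a fixed seed the files are byte-identical across runs.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "burden_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  tsv <- function(x, f) readr::write_tsv(x, path(f), progress = FALSE)

  variants <- sim$kb$variants
  write_cohort_vcf(
    variants[, c(
      "chrom", "pos", "ref", "alt", "consequence",
      "lof_confidence", "popmax_af"
    )],
    sim$calls, sim$samples, path("cohort.vcf")
  )
  tsv(
    tibble::tibble(
      chrom = sim$panel$chrom, start = sim$panel$start - 1L,
      end = sim$panel$end, gene = sim$panel$gene, strand = sim$panel$strand,
      inheritance = sim$panel$inheritance,
      lof_mechanism = sim$panel$lof_mechanism
    ),
    "panel.tsv"
  )
  vip_src <- variants[!is.na(variants$classification), ]
  tsv(
    tibble::tibble(
      Chrom = vip_src$chrom, Pos = vip_src$pos, Ref = vip_src$ref,
      Alt = vip_src$alt, Gene = vip_src$gene,
      Vip_variant_interpretation = vip_src$classification
    ),
    "vip.tsv"
  )
  cv <- sim$kb$clinvar
  cv_coord <- stringr::str_split_fixed(cv$key, ":", 4)
  tsv(
    tibble::tibble(
      Assembly = cv$assembly, GeneSymbol = cv$gene,
      ClinicalSignificance = cv$clinical_significance,
      ReviewStatus = cv$review_status,
      LastEvaluated = ifelse(
        is.na(cv$last_evaluated), "-",
        format(cv$last_evaluated, "%b %d, %Y")
      ),
      Chromosome = cv_coord[, 1], PositionVCF = cv_coord[, 2],
      ReferenceAlleleVCF = cv_coord[, 3], AlternateAlleleVCF = cv_coord[, 4]
    ),
    "clinvar.tsv"
  )
  fq <- sim$kb$freq
  fq_coord <- stringr::str_split_fixed(fq$key, ":", 4)
  tsv(
    tibble::tibble(
      Chrom = fq_coord[, 1], Pos = fq_coord[, 2], Ref = fq_coord[, 3],
      Alt = fq_coord[, 4], Gene = fq$gene, Population = fq$population,
      Subset = fq$subset, AC = fq$ac, AN = fq$an, Popmax_AF = fq$popmax_af
    ),
    "freq.tsv"
  )
  tsv(sim$ancestry, "ancestry.tsv")
  tsv(sim$ehr, "ehr.tsv")
  tsv(sim$survey, "survey.tsv")
  tsv(sim$truth, "truth.tsv")
  files <- c(
    vcf = path("cohort.vcf"), panel = path("panel.tsv"),
    vip = path("vip.tsv"), clinvar = path("clinvar.tsv"),
    freq = path("freq.tsv"), ancestry = path("ancestry.tsv"),
    ehr = path("ehr.tsv"), survey = path("survey.tsv"),
    truth = path("truth.tsv")
  )
  invisible(files)
}

#' Parameter-recovery report on a simulated cohort
#'
#' Runs the classification and statistics stages on a freshly simulated
#' cohort and compares the results with the planted truth: per-ancestry
#' positive-rate recovery (with a binomial CI check against the planted
#' expectation), gene-outlier detection sensitivity/specificity against the
#' genes planted with divergent rates, and the chi-square independence test
#' on the aggregated burden table.
#'
#' @param config A [sim_config()] object.
#' @param divergence_factor Planted-rate ratio (vs the reference group) above
#'   which a gene is considered truly divergent for the sensitivity
#'   calculation.
#' @param reference_group Reference ancestry group for the outlier scan.
#' @return A list: `rates` (per-group planted vs observed with CI check),
#'   `scan` (per-gene detection vs truth), `chisq` (test result),
#'   `sensitivity`, `specificity`.
#' @export
end_to_end_recovery <- function(config, divergence_factor = 2,
                                reference_group = "eur") {
  sim <- simulate_cohort(config)
  findings <- classify_cohort(
    sim$calls, sim$kb$vip, sim$panel,
    hfe_key = sim$kb$hfe_key, gq_threshold = config$gq_threshold
  )
  burden <- count_cohort(findings, sim$ancestry, panel = sim$panel)

  # expected positive rate: at least one planted finding whose GQ survives
  surv <- 1 - config$gq_below_frac
  planted <- config$rates |>
    dplyr::group_by(group = .data$ancestry) |>
    dplyr::summarise(
      planted_rate = 1 - prod(
        (1 - .data$plp_rate * surv) * (1 - .data$plof_rate * surv)
      ),
      .groups = "drop"
    )
  rates <- burden$overall |>
    dplyr::inner_join(planted, by = "group") |>
    dplyr::bind_cols(
      rate_with_ci(burden$overall$positives, burden$overall$n)[, c("ci_low", "ci_high")]
    ) |>
    dplyr::mutate(
      in_ci = .data$planted_rate >= .data$ci_low &
        .data$planted_rate <= .data$ci_high
    )

  scan <- gene_outlier_scan(burden, reference_group = reference_group)
  truth_div <- config$rates |>
    dplyr::inner_join(
      config$rates |>
        dplyr::filter(.data$ancestry == reference_group) |>
        dplyr::select("gene", ref_plp = "plp_rate"),
      by = "gene"
    ) |>
    dplyr::filter(.data$ancestry != reference_group) |>
    dplyr::mutate(divergent = .data$plp_rate >= divergence_factor * .data$ref_plp |
      .data$ref_plp >= divergence_factor * .data$plp_rate) |>
    dplyr::select("gene", group = "ancestry", "divergent")
  scan_eval <- scan |>
    dplyr::select("gene", "group", "significant") |>
    dplyr::inner_join(truth_div, by = c("gene", "group"))

  chisq <- chisq_independence(aggregate_for_chisq(burden))

  list(
    rates = rates,
    scan = scan_eval,
    chisq = chisq,
    sensitivity = mean(scan_eval$significant[scan_eval$divergent]),
    specificity = mean(!scan_eval$significant[!scan_eval$divergent])
  )
}
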