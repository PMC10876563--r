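test_that("padding is strand-aware, symmetric on request, and clipped at 1", {
  panel <- tibble::tibble(
    gene = c("PLUS", "MINUS", "EDGE"),
    chrom = "chr1",
    start = c(10000L, 10000L, 1500L),
    end = c(12000L, 12000L, 2000L),
    strand = c("+", "-", "+"),
    inheritance = "dominant_like",
    lof_mechanism = TRUE
  )
  padded <- pad_region(panel)
  expect_equal(
    unlist(padded[padded$gene == "PLUS", c("start", "end")], use.names = FALSE),
    c(8000L, 13000L)
  )
  expect_equal(
    unlist(padded[padded$gene == "MINUS", c("start", "end")], use.names = FALSE),
    c(9000L, 14000L)
  )
  expect_equal(padded$start[padded$gene == "EDGE"], 1L)

  sym <- pad_region(panel, strand_aware = FALSE)
  expect_equal(
    unlist(sym[sym$gene == "MINUS", c("start", "end")], use.names = FALSE),
    c(8000L, 13000L)
  )
})

test_that("padding uses the union envelope of multi-interval genes", {
  panel <- tibble::tibble(
    gene = "G", chrom = "chr1",
    start = c(10000L, 30000L), end = c(12000L, 31000L),
    strand = "+", inheritance = "dominant_like", lof_mechanism = TRUE
  )
  padded <- pad_region(panel)
  expect_equal(nrow(padded), 1)
  expect_equal(padded$start, 8000L)
  expect_equal(padded$end, 32000L)
})

test_that("the GQ filter is a strict inequality", {
  expect_equal(passes_gq(c(21, 20, 19, 0)), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(passes_gq(20, threshold = 19))
})

test_that("pLoF classification needs consequence, confidence and rarity together", {
  expect_true(is_plof("stop_gained", "high", 0.0005))
  expect_false(is_plof("stop_gained", "high", 0.001)) # threshold is strict
  expect_false(is_plof("missense_variant", "high", 0))
  expect_false(is_plof("stop_gained", "low", 0))
  expect_true(is_plof("frameshift_variant", "high", NA)) # absent = rare
  expect_equal(
    is_plof(
      c("stop_gained", "splice_donor_variant"), c("high", "high"),
      c(NA, 0.5)
    ),
    c(TRUE, FALSE)
  )
})

test_that("zygosity rules gate findings by inheritance mode", {
  panel <- tiny_panel()
  kb <- tiny_kb()
  classify <- function(calls) {
    suppressMessages(
      classify_cohort(calls, kb, panel, hfe_key = HFE_FIXTURE_KEY)
    )
  }

  # dominant-like: het knowledge-base P/LP call qualifies
  f <- classify(make_call("p1", "chr1", 15000, "A", "G", zygosity = "het"))
  expect_equal(f$category, "known_plp")

  # recessive: het does not qualify, hom does
  het <- classify(make_call("p1", "chr2", 15000, "G", "A", zygosity = "het"))
  expect_equal(nrow(het), 0)
  hom <- classify(make_call("p1", "chr2", 15000, "G", "A", zygosity = "hom_alt"))
  expect_equal(hom$category, "known_plp")

  # hfe_special: only the configured target variant, homozygous
  expect_equal(nrow(classify(
    make_call("p1", "chr3", 15000, "G", "A", zygosity = "het")
  )), 0)
  expect_equal(classify(
    make_call("p1", "chr3", 15000, "G", "A", zygosity = "hom_alt")
  )$category, "known_plp")
  # a different P/LP variant in the same gene never qualifies
  expect_equal(nrow(classify(
    make_call("p1", "chr3", 15100, "T", "C", zygosity = "hom_alt")
  )), 0)
})

test_that("pLoF findings split by knowledge-base overlap with correct precedence", {
  panel <- tiny_panel()
  kb <- tiny_kb()
  classify <- function(calls) {
    suppressMessages(
      classify_cohort(calls, kb, panel, hfe_key = HFE_FIXTURE_KEY)
    )
  }
  # novel high-confidence rare LoF in a LoF-mechanism gene
  novel <- classify(make_call("p1", "chr1", 16000, "C", "A",
    consequence = "stop_gained", lof_confidence = "high", popmax_af = 1e-4
  ))
  expect_equal(novel$category, "plof_novel")
  expect_true(novel$plof)
  # the same variant class in a non-LoF-mechanism gene yields nothing
  expect_equal(nrow(classify(make_call("p1", "chr2", 16000, "C", "A",
    consequence = "stop_gained", lof_confidence = "high", popmax_af = 1e-4
  ))), 0)
  # a KB P/LP variant that is also pLoF: known_plp wins in a dominant gene
  both <- classify(make_call("p1", "chr1", 15000, "A", "G",
    consequence = "frameshift_variant", lof_confidence = "high"
  ))
  expect_equal(both$category, "known_plp")
  expect_true(both$plof)
})

test_that("qualifying_findings rejects unfiltered or unsubsetted input", {
  panel <- tiny_panel()
  kb <- tiny_kb()
  call <- make_call("p1", "chr1", 15000, "A", "G", gq = 15)
  expect_error(qualifying_findings(call, kb), "subset_panel_calls")
  padded <- pad_region(panel)
  with_gene <- suppressMessages(subset_panel_calls(call, padded))
  expect_error(qualifying_findings(with_gene, kb), "GQ")
})

test_that("pipeline counts match the brute-force oracle on random cohorts", {
  panel <- tiny_panel()
  kb <- tiny_kb()
  for (seed in c(101, 202, 303)) {
    calls <- random_tiny_calls(
      n_participants = 100, n_variants = 50, seed = seed
    )
    got <- suppressMessages(
      classify_cohort(calls, kb, panel, hfe_key = HFE_FIXTURE_KEY)
    ) |>
      dplyr::select("participant_id", "gene", "key", "category") |>
      dplyr::arrange(.data$participant_id, .data$gene, .data$key) |>
      as.data.frame()
    want <- oracle_findings(calls, kb, panel, hfe_key = HFE_FIXTURE_KEY)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("permuting calls and relaxing GQ behave as invariants require", {
  panel <- tiny_panel()
  kb <- tiny_kb()
  calls <- random_tiny_calls(n_participants = 60, n_variants = 40, seed = 77)
  ancestry <- tibble::tibble(
    participant_id = sprintf("S%03d", 1:60),
    ancestry = rep(c("eur", "afr", "amr"), each = 20)
  )
  run <- function(cl, gq_threshold = 20) {
    f <- suppressMessages(classify_cohort(cl, kb, panel,
      hfe_key = HFE_FIXTURE_KEY, gq_threshold = gq_threshold
    ))
    count_cohort(f, ancestry, panel = panel)
  }
  base <- run(calls)
  set.seed(1)
  shuffled <- run(calls[sample(nrow(calls)), ])
  expect_equal(base$counts, shuffled$counts)
  expect_equal(base$overall, shuffled$overall)

  # removing the GQ filter can only increase every cell
  no_gq <- run(calls, gq_threshold = -1)
  expect_true(all(no_gq$counts$count >= base$counts$count))
})

test_that("burden counting uses distinct-participant semantics", {
  findings <- tibble::tibble(
    participant_id = c("p1", "p1", "p2"),
    gene = c("DOM1", "REC1", "DOM1"),
    key = c("k1", "k2", "k1"),
    zygosity = c("het", "hom_alt", "hom_alt"),
    category = c("known_plp", "known_plp", "plof_novel"),
    plof = c(FALSE, FALSE, TRUE)
  )
  ancestry <- tibble::tibble(
    participant_id = c("p1", "p2", "p3"),
    ancestry = c("eur", "eur", "afr")
  )
  bt <- count_cohort(findings, ancestry, panel = tiny_panel())
  wide <- burden_matrix(bt)
  # p1 contributes to two gene cells but once overall
  expect_equal(wide$eur[wide$gene == "DOM1"], 2L)
  expect_equal(wide$eur[wide$gene == "REC1"], 1L)
  expect_equal(bt$overall$positives[bt$overall$group == "eur"], 2L)
  expect_equal(bt$overall$rate[bt$overall$group == "afr"], 0)
  # denominators include finding-free participants
  expect_equal(bt$denominators$n, c(1L, 2L))
  # allele-instance mode weights homozygotes twice
  alleles <- count_cohort(findings, ancestry, panel = tiny_panel(), mode = "alleles")
  expect_equal(
    burden_matrix(alleles)$eur[burden_matrix(alleles)$gene == "DOM1"], 3L
  )
  # distinct-participant overall count never exceeds summed gene cells
  expect_true(sum(bt$overall$positives) <= sum(bt$counts$count))
  # empty findings give an all-zero table with intact denominators
  empty <- count_cohort(findings[0, ], ancestry, panel = tiny_panel())
  expect_true(all(burden_matrix(empty)[, -1] == 0))
  expect_equal(empty$denominators$n, c(1L, 2L))
})

test_that("participants without ancestry labels are excluded and reported", {
  findings <- tibble::tibble(
    participant_id = c("p1", "p9"), gene = "DOM1", key = "k1",
    zygosity = "het", category = "known_plp", plof = FALSE
  )
  ancestry <- tibble::tibble(participant_id = "p1", ancestry = "eur")
  expect_message(
    bt <- count_cohort(findings, ancestry),
    "lack an ancestry label"
  )
  expect_equal(bt$diagnostics$n_missing_ancestry, 1)
  expect_equal(sum(bt$counts$count), 1L)
  dup <- tibble::tibble(participant_id = c("p1", "p1"), ancestry = c("eur", "afr"))
  expect_error(count_cohort(findings, dup), "exactly one ancestry")
})

test_that("tidy and glance summarise a burden table", {
  findings <- tibble::tibble(
    participant_id = "p1", gene = "DOM1", key = "k1",
    zygosity = "het", category = "known_plp", plof = FALSE
  )
  ancestry <- tibble::tibble(
    participant_id = c("p1", "p2"), ancestry = c("eur", "eur")
  )
  bt <- count_cohort(findings, ancestry)
  td <- tidy(bt)
  expect_true(all(c("gene", "group", "count", "n", "rate") %in% names(td)))
  expect_equal(td$rate, 0.5)
  gl <- glance(bt)
  expect_equal(gl$n_participants, 2L)
  expect_equal(gl$positive_rate, 0.5)
})
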