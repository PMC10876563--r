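cv_record <- function(key, sig, status, date, assembly = "GRCh38", gene = "G1") {
  tibble::tibble(
    key = key, assembly = assembly, gene = gene,
    clinical_significance = sig, review_status = status,
    stars = clinvar_stars(status),
    last_evaluated = as.Date(date)
  )
}

# one record per filter branch, named by the behaviour it probes
clinvar_fixture <- function() {
  suppressWarnings(dplyr::bind_rows(
    cv_record("chr1:100:A:G", "Pathogenic", "criteria provided, multiple submitters, no conflicts", "2016-01-01"), # keep: 2* on cutoff day
    cv_record("chr1:101:A:G", "Pathogenic", "criteria provided, multiple submitters, no conflicts", "2015-12-31"), # drop: 2* stale
    cv_record("chr1:102:A:G", "Likely pathogenic", "criteria provided, multiple submitters, no conflicts", NA), # drop: 2* missing date
    cv_record("chr1:103:A:G", "Pathogenic", "reviewed by expert panel", "2010-06-01"), # keep: 3* any date
    cv_record("chr1:104:A:G", "Pathogenic, risk factor", "practice guideline", "2008-01-15"), # keep: 4* any date
    cv_record("chr1:105:A:G", "Conflicting interpretations of pathogenicity", "criteria provided, multiple submitters, no conflicts", "2020-01-01"), # drop: significance
    cv_record("chr1:106:A:G", "Pathogenic", "criteria provided, multiple submitters, no conflicts", "2020-01-01", assembly = "GRCh37"), # drop: assembly
    cv_record("chr1:107:A:G", "Uncertain significance", "reviewed by expert panel", "2020-01-01"), # drop: significance
    cv_record("chr1:108:A:G", "Pathogenic", "criteria provided, single submitter", "2020-01-01"), # drop: 1*
    cv_record("chr1:109:A:G", "Pathogenic/Likely pathogenic", "criteria provided, multiple submitters, no conflicts", "2019-03-01"), # keep -> Path
    cv_record("chr1:110:A:G", "Likely pathogenic, risk factor", "criteria provided, multiple submitters, no conflicts", "2018-07-01"), # keep -> LPath
    cv_record("chr1:111:A:G", "Benign", "practice guideline", "2020-01-01") # drop: significance
  ))
}

test_that("star ratings follow the standard review-status ladder", {
  fixture <- c(
    "practice guideline" = 4L,
    "reviewed by expert panel" = 3L,
    "criteria provided, multiple submitters, no conflicts" = 2L,
    "criteria provided, conflicting interpretations" = 1L,
    "criteria provided, single submitter" = 1L,
    "no assertion criteria provided" = 0L,
    "no assertion provided" = 0L,
    "no interpretation for the single variant" = 0L
  )
  expect_equal(clinvar_stars(names(fixture)), unname(fixture))
  # case/whitespace insensitive; unknown strings -> 0 with a warning
  expect_equal(clinvar_stars("  Practice Guideline "), 4L)
  expect_warning(s <- clinvar_stars("reviewed by somebody"), "unrecognized")
  expect_equal(s, 0L)
})

test_that("the P/LP filter keeps exactly the star/date/significance-qualified records", {
  records <- clinvar_fixture()
  kept <- suppressMessages(filter_clinvar_plp(records))
  expect_setequal(
    kept$key,
    c(
      "chr1:100:A:G", "chr1:103:A:G", "chr1:104:A:G",
      "chr1:109:A:G", "chr1:110:A:G"
    )
  )
  expect_true(all(kept$classification %in% c("Path", "LPath")))
  expect_equal(
    kept$classification[kept$key == "chr1:109:A:G"], "Path"
  )
  expect_equal(
    kept$classification[kept$key == "chr1:110:A:G"], "LPath"
  )
  # missing-date two-star records are reported
  expect_message(filter_clinvar_plp(records), "missing LastEvaluated")
})

test_that("the P/LP filter is monotone in the cutoff date", {
  records <- clinvar_fixture()
  base <- suppressMessages(filter_clinvar_plp(records, cutoff_date = "2016-01-01"))
  later <- suppressMessages(filter_clinvar_plp(records, cutoff_date = "2019-01-01"))
  expect_true(all(later$key %in% base$key))
  # 3/4-star records survive any cutoff
  far <- suppressMessages(filter_clinvar_plp(records, cutoff_date = "2030-01-01"))
  expect_setequal(far$key, c("chr1:103:A:G", "chr1:104:A:G"))
})

test_that("ClinVar TSV round trip preserves keys, stars and both date formats", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    Assembly = c("GRCh38", "GRCh38"),
    GeneSymbol = c("BRCA2", "LDLR"),
    ClinicalSignificance = c("Pathogenic", "Likely pathogenic"),
    ReviewStatus = c("practice guideline", "criteria provided, multiple submitters, no conflicts"),
    LastEvaluated = c("Jan 22, 2022", "2017-05-03"),
    Chromosome = c("13", "19"),
    PositionVCF = c(32315474L, 11089435L),
    ReferenceAlleleVCF = c("A", "C"),
    AlternateAlleleVCF = c("G", "T")
  ), path)
  cv <- read_clinvar(path)
  expect_equal(cv$key, c("chr13:32315474:A:G", "chr19:11089435:C:T"))
  expect_equal(cv$stars, c(4L, 2L))
  expect_equal(cv$last_evaluated, as.Date(c("2022-01-22", "2017-05-03")))
})

test_that("VIP loading keeps all classifications and rejects unknown or conflicting ones", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vip_tsv <- function(rows) {
    readr::write_tsv(rows, path)
    path
  }
  rows <- tibble::tibble(
    Chrom = c("1", "1", "2"), Pos = c(100L, 200L, 300L),
    Ref = c("A", "C", "G"), Alt = c("G", "T", "A"),
    Gene = c("BRCA2", "BRCA2", "LDLR"),
    Vip_variant_interpretation = c("Path", "VUS", "LPath")
  )
  kb <- read_vip(write_vip_tsv(rows))
  expect_equal(nrow(kb), 3)
  # VUS rows are loaded but excluded from the P/LP view
  expect_setequal(kb_plp(kb)$key, c("chr1:100:A:G", "chr2:300:G:A"))

  expect_error(
    read_vip(write_vip_tsv(dplyr::mutate(rows,
      Vip_variant_interpretation = c("Path", "pathogenic", "LPath")
    ))),
    "unknown interpretation"
  )
  conflicting <- dplyr::bind_rows(rows[1, ], dplyr::mutate(rows[1, ],
    Vip_variant_interpretation = "Benign"
  ))
  expect_error(read_vip(write_vip_tsv(conflicting)), "conflicting")

  empty <- read_vip(write_vip_tsv(rows[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("frequency joins keep unmatched P/LP variants as flagged-absent rows", {
  plp <- tibble::tibble(
    key = c("chr1:1:A:G", "chr1:2:A:G", "chr1:3:A:G"),
    gene = "G1", classification = "Path"
  )
  freq <- tibble::tibble(
    key = c("chr1:1:A:G", "chr1:2:A:G", "chr1:1:A:G"),
    gene = "G1",
    population = "eur",
    subset = c("full", "full", "non_cancer"),
    ac = c(5L, 2L, 3L), an = c(1000L, 900L, 800L), popmax_af = NA_real_
  )
  joined <- join_frequencies(plp, freq, "eur", "full")
  expect_equal(nrow(joined), 3)
  expect_equal(joined$ac[joined$key == "chr1:3:A:G"], 0L)
  expect_true(joined$absent[joined$key == "chr1:3:A:G"])
  # key-stability: matched + flagged-absent covers the whole P/LP set
  expect_equal(sum(!joined$absent) + sum(joined$absent), nrow(plp))
  # the same key under another subset is a distinct joined row
  other <- join_frequencies(plp, freq, "eur", "non_cancer")
  expect_equal(other$ac[other$key == "chr1:1:A:G"], 3L)

  dup <- dplyr::bind_rows(freq, freq[1, ])
  expect_error(join_frequencies(plp, dup, "eur", "full"), "duplicate")
})

test_that("population merging sums allele counts within key and subset", {
  freq <- tibble::tibble(
    key = "chr1:1:A:G", gene = "G1",
    population = c("nfe", "fin", "asj"),
    subset = "full",
    ac = c(10L, 2L, 1L), an = c(100L, 50L, 30L),
    popmax_af = c(0.1, NA, 0.2)
  )
  merged <- merge_populations(freq, list(eur = c("nfe", "fin", "asj")))
  expect_equal(merged$ac, 13L)
  expect_equal(merged$an, 180L)
  expect_equal(merged$population, "eur")
  expect_equal(merged$popmax_af, 0.2)
})
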