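test_that("the pooled z-test reproduces hand-checked reference comparisons", {
  # allele-count comparisons with known two-tailed p-values
  cases <- list(
    list(26, 71468, 34, 99336, 0.815),
    list(2, 82108, 5, 99336, 0.375),
    list(4964, 82106, 6371, 99336, 0.001)
  )
  for (cs in cases) {
    res <- two_proportion_z(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(round(res$p_value, 3), cs[[5]])
  }
  eq <- two_proportion_z(5, 100, 5, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
})

test_that("the pooled z-test matches prop.test and is antisymmetric", {
  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(50:5000, 1)
    n2 <- sample(50:5000, 1)
    y1 <- rbinom(1, n1, 0.05) + 1L
    y2 <- rbinom(1, n2, 0.08) + 1L
    res <- two_proportion_z(y1, n1, y2, n2)
    # z^2 equals the Pearson chi-square on the corresponding 2x2 table
    pt <- suppressWarnings(prop.test(c(y1, y2), c(n1, n2), correct = FALSE))
    expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-9)
    expect_equal(res$p_value, pt$p.value, tolerance = 1e-9)
    m22 <- matrix(c(y1, n1 - y1, y2, n2 - y2), nrow = 2, byrow = TRUE)
    expect_equal(res$z^2, oracle_pearson(m22), tolerance = 1e-9)
    # swapping groups negates z, preserves p
    rev <- two_proportion_z(y2, n2, y1, n1)
    expect_equal(rev$z, -res$z, tolerance = 1e-12)
    expect_equal(rev$p_value, res$p_value, tolerance = 1e-12)
    expect_equal(sign(res$z), sign(res$p_hat1 - res$p_hat2))
  }
})

test_that("growing samples at fixed unequal proportions shrinks the p-value", {
  p_prev <- 1
  for (scale in c(1, 2, 4, 8)) {
    res <- two_proportion_z(10 * scale, 1000 * scale, 20 * scale, 1000 * scale)
    expect_lt(res$p_value, p_prev)
    p_prev <- res$p_value
  }
})

test_that("degenerate pooled proportions are flagged, not divided by zero", {
  zz <- two_proportion_z(0, 50, 0, 500)
  expect_true(zz$degenerate)
  expect_equal(zz$p_value, 1)
  full <- two_proportion_z(50, 50, 500, 500)
  expect_true(full$degenerate)
  expect_error(two_proportion_z(5, 0, 1, 10), "positive")
  expect_error(two_proportion_z(11, 10, 1, 10), "0 <= y <= n")
})

test_that("Bonferroni thresholds divide the family-wise level", {
  expect_equal(bonferroni_alpha(0.05, 8), 0.00625)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 73), 0.05 / 73)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")
})

test_that("chi-square aggregation merges the configured groups then sparse genes", {
  # 3 groups with totals (100, 3, 2); merging the two smallest gives (100, 5)
  tab <- tibble::tibble(
    gene = c("A", "B"),
    eur = c(60L, 40L), eas = c(2L, 1L), mid = c(1L, 1L)
  )
  out <- aggregate_for_chisq(tab, min_expected = 0, collapse_groups = c("eas", "mid"))
  expect_equal(sort(names(out)), sort(c("gene", "eur", "aggregated")))
  expect_equal(sum(out$aggregated), 5)
  expect_equal(sum(out$eur), 100)

  # identity when the rule already holds and nothing is collapsed
  big <- tibble::tibble(gene = c("A", "B"), eur = c(50, 60), afr = c(40, 30))
  expect_equal(
    aggregate_for_chisq(big, collapse_groups = character(0)),
    big
  )

  # random tables: grand total and retained-group totals conserved
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(rpois(70, lambda = 8), nrow = 10)
    colnames(m) <- c("afr", "amr", "eas", "eur", "mid", "sas", "oth")
    tb <- dplyr::bind_cols(gene = paste0("g", 1:10), tibble::as_tibble(m))
    agg <- aggregate_for_chisq(tb)
    expect_equal(sum(agg[, -1]), sum(m))
    expect_equal(sum(agg$afr), sum(m[, "afr"]))
    expect_equal(sum(agg$eur), sum(m[, "eur"]))
    # expected-count rule holds on the result
    mm <- as.matrix(agg[, -1])
    expect_true(all(outer(rowSums(mm), colSums(mm)) / sum(mm) >= 5))
  }

  sparse <- tibble::tibble(gene = c("A", "B"), eur = c(1L, 1L), afr = c(1L, 0L))
  expect_error(
    aggregate_for_chisq(sparse, collapse_groups = character(0)),
    "cannot satisfy"
  )
})

test_that("chi-square independence matches the hand-computed Pearson statistic", {
  flat <- matrix(c(10, 10, 10, 10), nrow = 2)
  res <- chisq_independence(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  m <- matrix(c(20, 10, 10, 20), nrow = 2, byrow = TRUE)
  res2 <- chisq_independence(m)
  expect_equal(res2$statistic, oracle_pearson(m), tolerance = 1e-12)
  expect_equal(res2$df, 1)

  expect_error(chisq_independence(matrix(c(0, 0, 5, 5), nrow = 2)), "all-zero")
  expect_error(
    chisq_independence(matrix(c(1, 2, 2, 1), nrow = 2)),
    "aggregate"
  )
})

test_that("Wilson intervals match a score-test-inversion oracle", {
  zero <- rate_with_ci(0, 100)
  expect_equal(zero$rate, 0)
  expect_equal(zero$ci_low, 0)
  half <- rate_with_ci(50, 100)
  expect_equal(half$rate - half$ci_low, half$ci_high - half$rate,
    tolerance = 1e-9
  )
  for (cs in list(c(226, 10000), c(3, 50), c(49, 50), c(1, 100000))) {
    got <- rate_with_ci(cs[1], cs[2])
    want <- oracle_wilson(cs[1], cs[2])
    expect_lt(abs(got$ci_low - want[1]), 1e-9)
    expect_lt(abs(got$ci_high - want[2]), 1e-9)
    expect_true(got$ci_low <= got$rate && got$rate <= got$ci_high)
  }
  wald <- rate_with_ci(5, 10, method = "normal")
  expect_equal(wald$ci_high - wald$rate,
    qnorm(0.975) * sqrt(0.5 * 0.5 / 10),
    tolerance = 1e-12
  )
  expect_error(rate_with_ci(1, 0), "positive")
})

make_burden <- function(counts_wide, denoms) {
  counts <- tidyr::pivot_longer(counts_wide, -gene,
    names_to = "group", values_to = "count"
  )
  structure(
    list(
      counts = counts,
      denominators = tibble::tibble(
        group = names(denoms), n = unname(denoms)
      ),
      overall = NULL, categories = NULL, mode = "participants",
      diagnostics = list()
    ),
    class = "burden_table"
  )
}

test_that("the outlier scan flags a planted divergent gene and skips empty ones", {
  set.seed(321)
  n_afr <- 20000
  n_eur <- 50000
  genes <- paste0("G", 1:8)
  base <- 0.001
  afr_rates <- rep(base, 8)
  afr_rates[3] <- 3 * base # planted divergence
  counts <- tibble::tibble(
    gene = genes,
    afr = rbinom(8, n_afr, afr_rates),
    eur = rbinom(8, n_eur, base)
  )
  counts$afr[8] <- 0L
  counts$eur[8] <- 0L # both-zero row must be skipped
  bt <- make_burden(counts, c(afr = n_afr, eur = n_eur))
  scan <- gene_outlier_scan(bt, reference_group = "eur")
  expect_true(scan$significant[scan$gene == "G3"])
  expect_false(any(scan$gene == "G8"))
  expect_equal(nrow(attr(scan, "skipped")), 1)
  expect_equal(unique(scan$m), nrow(scan))
  # z is oriented group-minus-reference
  expect_gt(scan$z[scan$gene == "G3"], 0)
})

test_that("the outlier scan rarely flags anything under the null", {
  set.seed(99)
  flagged_reps <- 0
  for (rep in 1:100) {
    counts <- tibble::tibble(
      gene = paste0("G", 1:6),
      afr = rbinom(6, 20000, 0.002),
      eur = rbinom(6, 50000, 0.002)
    )
    bt <- make_burden(counts, c(afr = 20000, eur = 50000))
    scan <- gene_outlier_scan(bt, reference_group = "eur")
    if (any(scan$significant)) flagged_reps <- flagged_reps + 1
  }
  expect_lte(flagged_reps / 100, 0.05)
})

test_that("the outlier scan requires the reference group", {
  bt <- make_burden(
    tibble::tibble(gene = "G1", afr = 5L),
    c(afr = 1000)
  )
  expect_error(gene_outlier_scan(bt, reference_group = "eur"), "not present")
})
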