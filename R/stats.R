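#' Pooled two-proportion z-test
#'
#' Tests equality of two binomial proportions with the pooled-variance
#' z statistic
#' \deqn{Z = \frac{\hat p_1 - \hat p_2}{\sqrt{\hat p (1-\hat p)
#'   (1/n_1 + 1/n_2)}}, \qquad
#'   \hat p = \frac{Y_1 + Y_2}{n_1 + n_2},}
#' where \eqn{Y_i} are the group counts, \eqn{n_i} the group totals and
#' \eqn{\hat p_i = Y_i / n_i} the group proportions. The p-value is the
#' two-tailed normal tail probability \eqn{2(1 - \Phi(|Z|))}. When the
#' pooled proportion is exactly 0 or 1 the statistic has zero variance; the
#' result is returned as `z = 0`, `p_value = 1` with `degenerate = TRUE`
#' rather than a division error.
#'
#' All arguments are vectorized.
#'
#' @param y1,n1 Count and total for group 1.
#' @param y2,n2 Count and total for group 2.
#' @return A tibble with one row per comparison: `y1`, `n1`, `y2`, `n2`,
#'   `p_hat1`, `p_hat2`, `p_hat` (pooled), `z`, `p_value`, `degenerate`.
#'   `z` carries the sign of `p_hat1 - p_hat2`.
#' @examples
#' two_proportion_z(26, 71468, 34, 99336) # p ~ 0.815
#' @export
two_proportion_z <- function(y1, n1, y2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("group totals n1, n2 must be positive", call. = FALSE)
  }
  if (any(y1 < 0) || any(y2 < 0) || any(y1 > n1) || any(y2 > n2)) {
    stop("counts must satisfy 0 <= y <= n", call. = FALSE)
  }
  p1 <- y1 / n1
  p2 <- y2 / n2
  pooled <- (y1 + y2) / (n1 + n2)
  degenerate <- pooled <= 0 | pooled >= 1
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(degenerate, 0, (p1 - p2) / se)
  p_value <- ifelse(degenerate, 1, 2 * stats::pnorm(-abs(z)))
  tibble::tibble(
    y1 = y1, n1 = n1, y2 = y2, n2 = n2,
    p_hat1 = p1, p_hat2 = p2, p_hat = pooled,
    z = z, p_value = p_value, degenerate = degenerate
  )
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons in the family (`m >= 1`).
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 8) # 0.00625
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (any(m < 1)) stop("Bonferroni family size m must be >= 1", call. = FALSE)
  alpha / m
}

#' Aggregate sparse rows and columns for a valid chi-square test
#'
#' Prepares a gene x ancestry-group count table for the chi-square
#' independence test, which requires every expected cell count to be at
#' least `min_expected`. Two steps are applied:
#'
#' 1. the listed under-represented ancestry groups are merged into a single
#'    `"aggregated"` column;
#' 2. genes are merged, smallest row total first (ties broken by gene name),
#'    into a single `"aggregated"` row until all expected counts under
#'    independence reach `min_expected`.
#'
#' The grand total and the totals of retained groups are conserved.
#'
#' @param x A `burden_table`, a long counts tibble, or a wide gene-by-group
#'   tibble as produced by [burden_matrix()].
#' @param min_expected Minimum expected cell count (default 5).
#' @param collapse_groups Ancestry groups to merge unconditionally; default
#'   the four least-represented groups (`eas`, `mid`, `sas`, `oth`). Groups
#'   not present are ignored.
#' @return A wide tibble (gene rows x group columns) satisfying the
#'   expected-count rule.
#' @export
aggregate_for_chisq <- function(x, min_expected = 5,
                                collapse_groups = c("eas", "mid", "sas", "oth")) {
  wide <- if (inherits(x, "burden_table") ||
    all(c("gene", "group", "count") %in% names(x))) {
    burden_matrix(x)
  } else {
    tibble::as_tibble(x)
  }
  mat <- as.matrix(wide[, setdiff(names(wide), "gene"), drop = FALSE])
  rownames(mat) <- wide$gene

  merge_cols <- intersect(collapse_groups, colnames(mat))
  if (length(merge_cols) > 1) {
    keep <- setdiff(colnames(mat), merge_cols)
    mat <- cbind(
      mat[, keep, drop = FALSE],
      aggregated = rowSums(mat[, merge_cols, drop = FALSE])
    )
  } else if (length(merge_cols) == 1) {
    colnames(mat)[colnames(mat) == merge_cols] <- "aggregated"
  }

  expected_ok <- function(m) {
    total <- sum(m)
    if (total == 0) {
      return(FALSE)
    }
    exp_m <- outer(rowSums(m), colSums(m)) / total
    all(exp_m >= min_expected)
  }

  while (!expected_ok(mat)) {
    candidates <- setdiff(rownames(mat), "aggregated")
    if (length(candidates) == 0 ||
      (length(candidates) == 1 && !"aggregated" %in% rownames(mat))) {
      stop(
        "table cannot satisfy the expected-count rule even fully aggregated",
        call. = FALSE
      )
    }
    totals <- rowSums(mat[candidates, , drop = FALSE])
    victim <- candidates[order(totals, candidates)][1]
    if ("aggregated" %in% rownames(mat)) {
      mat["aggregated", ] <- mat["aggregated", ] + mat[victim, ]
      mat <- mat[setdiff(rownames(mat), victim), , drop = FALSE]
    } else {
      rownames(mat)[rownames(mat) == victim] <- "aggregated"
    }
    if (nrow(mat) < 2) {
      stop(
        "table cannot satisfy the expected-count rule even fully aggregated",
        call. = FALSE
      )
    }
  }

  dplyr::bind_cols(
    tibble::tibble(gene = rownames(mat)),
    tibble::as_tibble(mat)
  )
}

#' Chi-square test of independence on a collapsed burden table
#'
#' Pearson chi-square without continuity correction on a gene x group count
#' table, with `df = (rows - 1)(cols - 1)`. The table must already satisfy
#' the expected-count rule; use [aggregate_for_chisq()] first.
#'
#' @param x A wide gene-by-group tibble (optionally with a `gene` column) or
#'   a numeric matrix.
#' @param min_expected Validity threshold checked before testing.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n` (grand
#'   total).
#' @export
chisq_independence <- function(x, min_expected = 5) {
  if (is.data.frame(x)) {
    mat <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
    rownames(mat) <- if ("gene" %in% names(x)) x$gene else NULL
  } else {
    mat <- as.matrix(x)
  }
  if (any(rowSums(mat) == 0) || any(colSums(mat) == 0)) {
    stop("table has an all-zero row or column", call. = FALSE)
  }
  expected <- outer(rowSums(mat), colSums(mat)) / sum(mat)
  if (any(expected < min_expected)) {
    stop(
      "expected cell counts below ", min_expected,
      "; aggregate with aggregate_for_chisq() first",
      call. = FALSE
    )
  }
  ht <- stats::chisq.test(mat, correct = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    n = sum(mat)
  )
}

#' Scan genes for ancestry groups with outlying pathogenic rates
#'
#' Compares each gene's per-group carrier proportion against the reference
#' ancestry group with the pooled two-proportion z-test, Bonferroni-adjusting
#' the family of all comparisons actually performed. Gene/group pairs where
#' both the tested group and the reference have zero carriers are skipped
#' (their keys are recorded in the `skipped` attribute); the reference group
#' is never compared with itself.
#'
#' @param burden A `burden_table` ([count_cohort()] output).
#' @param reference_group Ancestry group used as the reference (default
#'   `"eur"`).
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Bonferroni family size; defaults to the number of comparisons
#'   performed. Override to impose an external family.
#' @return A tibble with one row per gene x non-reference group:
#'   the [two_proportion_z()] columns (group 1 = tested group, group 2 =
#'   reference) plus `gene`, `group`, `m`, `alpha_adjusted` and
#'   `significant` (`p_value < alpha / m`).
#' @export
gene_outlier_scan <- function(burden, reference_group = "eur", alpha = 0.05,
                              m = NULL) {
  tab <- tidy(burden)
  if (!reference_group %in% tab$group) {
    stop("reference group '", reference_group, "' not present", call. = FALSE)
  }
  ref <- tab |>
    dplyr::filter(.data$group == reference_group) |>
    dplyr::select("gene", ref_count = "count", ref_n = "n")
  tests <- tab |>
    dplyr::filter(.data$group != reference_group) |>
    dplyr::inner_join(ref, by = "gene")
  skip <- tests$count == 0 & tests$ref_count == 0
  skipped <- tests[skip, c("gene", "group")]
  tests <- tests[!skip, , drop = FALSE]
  if (nrow(tests) == 0) {
    stop("no informative gene/group comparisons to perform", call. = FALSE)
  }
  m <- m %||% nrow(tests)
  alpha_adj <- bonferroni_alpha(alpha, m)
  out <- dplyr::bind_cols(
    tests[, c("gene", "group")],
    two_proportion_z(tests$count, tests$n, tests$ref_count, tests$ref_n)
  ) |>
    dplyr::mutate(
      m = m,
      alpha_adjusted = alpha_adj,
      significant = .data$p_value < alpha_adj
    )
  attr(out, "skipped") <- skipped
  attr(out, "reference_group") <- reference_group
  out
}

#' Binomial rate with confidence interval
#'
#' Point estimate and confidence interval for a carrier rate. The default
#' Wilson score interval behaves well at the small counts typical of rare
#' pathogenic variants (it never escapes `[0, 1]` and has no zero-width
#' collapse at 0 successes); a normal-approximation (Wald) interval is
#' selectable for comparison.
#'
#' @param count,n Successes and trials (vectorized; `n > 0`).
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"normal"`.
#' @return A tibble: `count`, `n`, `rate`, `ci_low`, `ci_high`, `level`,
#'   `method`.
#' @export
rate_with_ci <- function(count, n, level = 0.95,
                         method = c("wilson", "normal")) {
  method <- match.arg(method)
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(count < 0) || any(count > n)) {
    stop("count must satisfy 0 <= count <= n", call. = FALSE)
  }
  p <- count / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wilson") {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    lo <- centre - half
    hi <- centre + half
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  }
  tibble::tibble(
    count = count, n = n, rate = p,
    ci_low = pmax(0, lo), ci_high = pmin(1, hi),
    level = level, method = method
  )
}
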