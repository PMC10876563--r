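# Independent oracles and tiny fixtures shared across tests. The oracles are
# deliberately written as direct transcriptions of the definitions (nested
# loops, numeric root-finding) rather than reusing package internals.

# Wilson interval bounds by numerically inverting the score test:
# the bounds solve (phat - p)^2 = z^2 p (1 - p) / n.
oracle_wilson <- function(count, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- count / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  eps <- 1e-12
  lo <- if (f(eps) < 0) eps else uniroot(f, c(eps, max(phat, eps)), tol = 1e-12)$root
  hi <- if (f(1 - eps) < 0) {
    1 - eps
  } else {
    uniroot(f, c(min(phat, 1 - eps), 1 - eps), tol = 1e-12)$root
  }
  c(lo, hi)
}

# Pearson chi-square statistic by explicit expected-count loops.
oracle_pearson <- function(mat) {
  total <- sum(mat)
  stat <- 0
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      e <- sum(mat[i, ]) * sum(mat[, j]) / total
      stat <- stat + (mat[i, j] - e)^2 / e
    }
  }
  stat
}

LOF_TERMS <- c(
  "frameshift_variant", "stop_gained", "stop_lost",
  "splice_acceptor_variant", "splice_donor_variant", "start_lost"
)

# Brute-force finding classifier: one explicit pass over every
# call x panel-gene pair, applying each rule independently.
oracle_findings <- function(calls, kb, panel, hfe_key = NULL,
                            gq_threshold = 20, af_threshold = 0.001,
                            upstream = 2000, downstream = 1000) {
  plp_keys <- kb$key[kb$classification %in% c("Path", "LPath")]
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (!(cl$gq > gq_threshold)) next
    for (j in seq_len(nrow(panel))) {
      g <- panel[j, ]
      left <- if (g$strand == "+") upstream else downstream
      right <- if (g$strand == "+") downstream else upstream
      if (cl$chrom != g$chrom) next
      if (cl$pos < max(1, g$start - left) || cl$pos > g$end + right) next
      in_kb <- cl$key %in% plp_keys
      plof <- cl$consequence %in% LOF_TERMS &&
        identical(cl$lof_confidence, "high") &&
        (is.na(cl$popmax_af) || cl$popmax_af < af_threshold)
      known <- FALSE
      if (in_kb) {
        if (g$inheritance == "dominant_like") known <- TRUE
        if (g$inheritance == "recessive_homozygous_only" &&
          cl$zygosity == "hom_alt") {
          known <- TRUE
        }
        if (g$inheritance == "hfe_special" && cl$zygosity == "hom_alt" &&
          !is.null(hfe_key) && cl$key == hfe_key) {
          known <- TRUE
        }
      }
      category <- if (known) {
        "known_plp"
      } else if (plof && g$lof_mechanism && in_kb) {
        "plof_known_overlap"
      } else if (plof && g$lof_mechanism) {
        "plof_novel"
      } else {
        NA_character_
      }
      if (!is.na(category)) {
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = cl$participant_id, gene = g$gene, key = cl$key,
          category = category, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(
      participant_id = character(), gene = character(),
      key = character(), category = character()
    ))
  }
  out[order(out$participant_id, out$gene, out$key), , drop = FALSE]
}

tiny_panel <- function() {
  tibble::tibble(
    gene = c("DOM1", "REC1", "HFE"),
    chrom = c("chr1", "chr2", "chr3"),
    start = c(10000L, 10000L, 10000L),
    end = c(20000L, 20000L, 20000L),
    strand = c("+", "-", "+"),
    inheritance = c("dominant_like", "recessive_homozygous_only", "hfe_special"),
    lof_mechanism = c(TRUE, FALSE, FALSE)
  )
}

tiny_kb <- function() {
  tibble::tibble(
    key = c(
      "chr1:15000:A:G", "chr1:15100:C:T", "chr2:15000:G:A",
      "chr3:15000:G:A", "chr3:15100:T:C"
    ),
    gene = c("DOM1", "DOM1", "REC1", "HFE", "HFE"),
    classification = c("Path", "VUS", "LPath", "Path", "Path"),
    hgvs_c = NA_character_,
    source = "fixture"
  )
}

HFE_FIXTURE_KEY <- "chr3:15000:G:A"

make_call <- function(participant_id, chrom, pos, ref, alt,
                      zygosity = "het", gq = 60,
                      consequence = "missense_variant",
                      lof_confidence = "missing", popmax_af = NA_real_) {
  tibble::tibble(
    participant_id = participant_id,
    key = variant_key(chrom, pos, ref, alt),
    chrom = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
    pos = as.integer(pos), ref = toupper(ref), alt = toupper(alt),
    zygosity = zygosity, gq = gq, consequence = consequence,
    lof_confidence = lof_confidence, popmax_af = popmax_af
  )
}

# Random small cohorts over the tiny panel for oracle-equivalence checks.
random_tiny_calls <- function(n_participants, n_variants, seed) {
  set.seed(seed)
  panel <- tiny_panel()
  kb <- tiny_kb()
  known_pos <- as.integer(sub("^chr\\d+:(\\d+):.*$", "\\1", kb$key))
  known_chrom <- sub("^(chr\\d+):.*$", "\\1", kb$key)
  ids <- sprintf("S%03d", seq_len(n_participants))
  rows <- lapply(seq_len(n_variants), function(i) {
    if (runif(1) < 0.4) {
      j <- sample(nrow(kb), 1)
      chrom <- known_chrom[j]
      pos <- known_pos[j]
      ref <- sub("^.*:(\\w+):(\\w+)$", "\\1", kb$key[j])
      alt <- sub("^.*:(\\w+):(\\w+)$", "\\2", kb$key[j])
    } else {
      g <- panel[sample(nrow(panel), 1), ]
      chrom <- g$chrom
      pos <- sample(seq(g$start - 3000, g$end + 3000), 1)
      ref <- sample(c("A", "C"), 1)
      alt <- sample(c("G", "T"), 1)
    }
    carriers <- sample(ids, sample(1:5, 1))
    make_call(
      carriers, chrom, pos, ref, alt,
      zygosity = sample(c("het", "hom_alt"), length(carriers), replace = TRUE),
      gq = sample(10:80, length(carriers), replace = TRUE),
      consequence = sample(c(LOF_TERMS, "missense_variant", "synonymous_variant"), 1),
      lof_confidence = sample(c("high", "low", "missing"), 1),
      popmax_af = sample(c(NA_real_, 1e-5, 5e-4, 0.002, 0.01), 1)
    )
  })
  calls <- dplyr::bind_rows(rows)
  dplyr::distinct(calls, participant_id, key, .keep_all = TRUE)
}
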