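#' Read per-sample genotype calls from a cohort VCF
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) into a long tibble of non-reference
#' genotype calls, one row per participant x variant allele. The `GT` and
#' `GQ` FORMAT fields are required. Consequence annotations are read from a
#' pipe-delimited, CSQ-style INFO field; the subfield names holding the
#' allele, the most severe consequence, the LoF confidence flag and the
#' popmax allele frequency are configurable. Multi-allelic records are
#' decomposed into one call per ALT allele; genotypes carrying two copies of
#' an ALT (including haploid/hemizygous single-allele genotypes) are recorded
#' as `hom_alt`, one copy as `het`.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param csq_tag INFO tag carrying the annotation string (default `"CSQ"`).
#' @param csq_fields Character vector naming, in order, the pipe-delimited
#'   subfields; must contain `"Allele"`, `"Consequence"`, `"LoF"` and
#'   `"PopmaxAF"` (LoF values `HC`/`LC` map to confidence `high`/`low`).
#' @return A tibble with columns `participant_id`, `key`, `chrom`, `pos`,
#'   `ref`, `alt`, `zygosity` (`het`/`hom_alt`), `gq`, `consequence`,
#'   `lof_confidence` (`high`/`low`/`missing`), `popmax_af`.
#' @export
read_cohort_vcf <- function(path, csq_tag = "CSQ",
                            csq_fields = c("Allele", "Consequence", "LoF", "PopmaxAF")) {
  needed <- c("Allele", "Consequence", "LoF", "PopmaxAF")
  if (!all(needed %in% csq_fields)) {
    stop("csq_fields must include: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  csq <- vcfR::extract.info(vcf, element = csq_tag)
  samples <- colnames(gt)

  idx <- list(
    allele = match("Allele", csq_fields),
    cons = match("Consequence", csq_fields),
    lof = match("LoF", csq_fields),
    af = match("PopmaxAF", csq_fields)
  )

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ann <- parse_csq_entries(csq[i], alts, idx)
    gt_i <- gt[i, ]
    gq_i <- gq[i, ]
    called <- !is.na(gt_i) & !gt_i %in% c("0/0", "0|0", ".", "./.", ".|.", "0")
    if (!any(called)) next
    codes <- strsplit(gsub("|", "/", gt_i[called], fixed = TRUE), "/", fixed = TRUE)
    per_alt <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      n_alt <- vapply(codes, function(x) sum(x == as.character(k)), integer(1))
      haploid <- lengths(codes) == 1L & n_alt == 1L
      n_alt[haploid] <- 2L # hemizygous counted as hom_alt
      hit <- n_alt > 0L
      if (!any(hit)) next
      per_alt[[k]] <- tibble::tibble(
        participant_id = unname(samples[called][hit]),
        chrom = unname(fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = unname(fix[i, "REF"]),
        alt = alts[k],
        zygosity = unname(ifelse(n_alt[hit] >= 2L, "hom_alt", "het")),
        gq = unname(as.numeric(gq_i[called][hit])),
        consequence = ann$consequence[k],
        lof_confidence = ann$lof_confidence[k],
        popmax_af = ann$popmax_af[k]
      )
    }
    out[[i]] <- dplyr::bind_rows(per_alt)
  }
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0) {
    return(tibble::tibble(
      participant_id = character(), key = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      zygosity = character(), gq = numeric(), consequence = character(),
      lof_confidence = character(), popmax_af = numeric()
    ))
  }
  calls$key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  dplyr::relocate(calls, "participant_id", "key")
}

parse_csq_entries <- function(csq_string, alts, idx) {
  n <- length(alts)
  cons <- rep(NA_character_, n)
  lof <- rep("missing", n)
  af <- rep(NA_real_, n)
  if (!is.na(csq_string) && nzchar(csq_string)) {
    entries <- strsplit(csq_string, ",", fixed = TRUE)[[1]]
    for (e in entries) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      k <- match(f[idx$allele], alts)
      if (is.na(k)) next
      cons[k] <- f[idx$cons]
      lof_raw <- if (length(f) >= idx$lof) f[idx$lof] else ""
      lof[k] <- switch(lof_raw, HC = "high", LC = "low", "missing")
      af_raw <- if (length(f) >= idx$af) f[idx$af] else ""
      af[k] <- if (nzchar(af_raw)) suppressWarnings(as.numeric(af_raw)) else NA_real_
    }
  }
  list(consequence = cons, lof_confidence = lof, popmax_af = af)
}

#' Write a synthetic cohort VCF
#'
#' Serializes a variant table plus a long table of non-reference calls into a
#' VCF 4.2 text file with `GT:GQ` FORMAT fields and a CSQ-style annotation
#' INFO field (`Allele|Consequence|LoF|PopmaxAF`). Samples without a call at
#' a site are written as `0/0` with a fixed nominal GQ. Contigs are declared
#' explicitly in the header from the variant table.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `lof_confidence`, `popmax_af` (one ALT per row).
#' @param calls Tibble with columns `participant_id`, `key`, `zygosity`,
#'   `gq`.
#' @param samples Character vector of all sample ids (column order).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, calls, samples, path) {
  variants <- variants |>
    dplyr::mutate(
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  contigs <- unique(variants$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ancestryburden-simulator",
    paste0("##contig=<ID=", contigs, ">"),
    paste0(
      "##INFO=<ID=CSQ,Number=.,Type=String,Description=",
      "\"Consequence annotations. Format: Allele|Consequence|LoF|PopmaxAF\">"
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )

  gt_code <- c(het = "0/1", hom_alt = "1/1")
  body <- character(nrow(variants))
  call_split <- split(calls, calls$key)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    lc <- v$lof_confidence
    if (is.na(lc)) lc <- "missing"
    csq <- paste(
      v$alt,
      ifelse(is.na(v$consequence), "", v$consequence),
      switch(lc, high = "HC", low = "LC", ""),
      ifelse(is.na(v$popmax_af), "", format(v$popmax_af, scientific = FALSE)),
      sep = "|"
    )
    geno <- rep("0/0:50", length(samples))
    names(geno) <- samples
    vc <- call_split[[v$key]]
    if (!is.null(vc)) {
      geno[vc$participant_id] <- paste0(gt_code[vc$zygosity], ":", vc$gq)
    }
    body[i] <- paste(c(
      v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
      paste0("CSQ=", csq), "GT:GQ", geno
    ), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
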