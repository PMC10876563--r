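#' Build canonical variant keys
#'
#' All joins between the cohort, the curated knowledge base, ClinVar and the
#' population-frequency tables use a chromosome-position-ref-alt string as the
#' primary key. `variant_key()` canonicalizes its inputs (chromosome prefixed
#' with `"chr"`, alleles uppercased) and validates them. No indel
#' renormalization or shared-prefix trimming is performed: records are joined
#' exactly as published, so representation mismatches surface downstream as
#' flagged-absent rows rather than being silently repaired.
#'
#' @param chrom Chromosome names; `"1"` and `"chr1"` map to the same key.
#' @param pos 1-based position of the first REF base (VCF convention).
#' @param ref,alt REF and ALT allele strings (`[ACGT]+`); case-insensitive.
#'
#' @return A character vector of keys of the form `"chr22:36265860:A:G"`.
#' @examples
#' variant_key("22", 36265860, "A", "G")
#' variant_key("chr1", 100, "a", "t")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- as.character(chrom)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("`pos` must be a positive 1-based integer position", call. = FALSE)
  }
  bad_ref <- !grepl("^[ACGT]+$", ref)
  if (any(bad_ref)) {
    stop(
      "malformed `ref` allele(s): ",
      paste(unique(ref[bad_ref]), collapse = ", "),
      call. = FALSE
    )
  }
  bad_alt <- !grepl("^[ACGT]+$", alt)
  if (any(bad_alt)) {
    stop(
      "malformed `alt` allele(s): ",
      paste(unique(alt[bad_alt]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(ref == alt)) {
    stop("`ref` and `alt` must differ (found ref == alt)", call. = FALSE)
  }
  chrom <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Add a canonical variant key column to a table
#'
#' Convenience wrapper applying [variant_key()] to the four coordinate
#' columns of a data frame.
#'
#' @param data A data frame with chromosome/position/ref/alt columns.
#' @param chrom,pos,ref,alt Column names (strings) holding the coordinates.
#' @return `data` as a tibble with a `key` column prepended.
#' @export
add_variant_key <- function(data, chrom = "chrom", pos = "pos",
                            ref = "ref", alt = "alt") {
  data <- tibble::as_tibble(data)
  key <- variant_key(data[[chrom]], data[[pos]], data[[ref]], data[[alt]])
  dplyr::bind_cols(tibble::tibble(key = key), data)
}
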