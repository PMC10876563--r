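#' Read an actionable-gene panel file
#'
#' The panel is a BED-like TSV describing the coding envelope of each gene in
#' the reporting panel: columns `chrom`, `start` (0-based half-open, BED
#' convention), `end`, `gene`, `strand` (`+`/`-`), `inheritance`
#' (`dominant_like`, `recessive_homozygous_only`, `hfe_special`) and
#' `lof_mechanism` (`TRUE` for genes where loss of function is a recognized
#' disease mechanism, so novel pLoF variants count as findings). A gene may
#' span several rows (one per coding interval).
#'
#' @param path Path to the panel TSV (with header).
#' @return A tibble with 1-based closed coordinates (`start`, `end`).
#' @export
read_panel <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("chrom", "start", "end", "gene", "strand", "inheritance", "lof_mechanism")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("panel file is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  panel <- tibble::tibble(
    gene = as.character(raw$gene),
    chrom = ifelse(grepl("^chr", raw$chrom), raw$chrom, paste0("chr", raw$chrom)),
    start = as.integer(raw$start) + 1L, # BED half-open -> 1-based closed
    end = as.integer(raw$end),
    strand = as.character(raw$strand),
    inheritance = as.character(raw$inheritance),
    lof_mechanism = as.logical(raw$lof_mechanism)
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(all(c(
    "gene", "chrom", "start", "end", "strand",
    "inheritance", "lof_mechanism"
  ) %in% names(panel)))
  if (!all(panel$strand %in% c("+", "-"))) {
    stop("panel strand must be '+' or '-'", call. = FALSE)
  }
  bad <- setdiff(unique(panel$inheritance), INHERITANCE_MODES)
  if (length(bad) > 0) {
    stop("unknown inheritance mode(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(panel$end < panel$start)) {
    stop("panel intervals must satisfy start <= end", call. = FALSE)
  }
  invisible(panel)
}

#' Pad panel regions up- and downstream of the coding envelope
#'
#' Widens each gene's coding envelope so that regulatory and near-gene
#' pathogenic variants are not excluded by coding-only subsetting. Padding is
#' applied to the union envelope of the gene's coding intervals. By default
#' it is strand-aware: "upstream" means the 5' side of the transcription
#' strand, so on the minus strand the upstream pad extends to higher
#' coordinates. `strand_aware = FALSE` gives coordinate-symmetric padding
#' (upstream pad on the lower-coordinate side for every gene). Padded starts
#' are clipped at position 1.
#'
#' @param panel A panel tibble ([read_panel()] output; 1-based closed).
#' @param upstream_bp,downstream_bp Pad widths in base pairs (defaults 2000
#'   upstream, 1000 downstream).
#' @param strand_aware Interpret up/downstream relative to the gene strand.
#' @return One row per gene: `gene`, `chrom`, `start`, `end` (padded,
#'   1-based closed), `strand`, `inheritance`, `lof_mechanism`.
#' @examples
#' panel <- tibble::tibble(
#'   gene = "G", chrom = "chr1", start = 10000L, end = 12000L,
#'   strand = "+", inheritance = "dominant_like", lof_mechanism = TRUE
#' )
#' pad_region(panel)
#' @export
pad_region <- function(panel, upstream_bp = 2000, downstream_bp = 1000,
                       strand_aware = TRUE) {
  validate_panel(panel)
  env <- panel |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      strand = dplyr::first(.data$strand),
      inheritance = dplyr::first(.data$inheritance),
      lof_mechanism = dplyr::first(.data$lof_mechanism),
      .groups = "drop"
    )
  minus <- strand_aware & env$strand == "-"
  left_pad <- ifelse(minus, downstream_bp, upstream_bp)
  right_pad <- ifelse(minus, upstream_bp, downstream_bp)
  env |>
    dplyr::mutate(
      start = pmax(1L, as.integer(.data$start - left_pad)),
      end = as.integer(.data$end + right_pad)
    )
}
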