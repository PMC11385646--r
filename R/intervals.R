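## Interval sets travel as tibbles with 0-based half-open coordinates
## (chrom, start, end, optional name/score); GRanges (1-based closed) is the
## internal engine for overlap arithmetic.

#' Convert an interval tibble (0-based half-open) to GRanges
#' @param x Tibble with columns chrom, start, end (0-based half-open).
#' @return A `GRanges`.
#' @export
intervals_to_granges <- function(x) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  if (any(x$start >= x$end)) abort("intervals must satisfy start < end.")
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  if ("name" %in% names(x)) S4Vectors::mcols(gr)$name <- x$name
  gr
}

#' Convert GRanges back to a 0-based half-open interval tibble
#' @param gr A `GRanges`.
#' @return Tibble with chrom, start, end (+ name when present).
#' @export
granges_to_intervals <- function(gr) {
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc) && !all(is.na(mc$name))) out$name <- mc$name
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Read a BED file as an interval tibble
#'
#' BED is 0-based half-open on disk; the returned tibble keeps that
#' convention.
#'
#' @param path BED file path.
#' @return Tibble with chrom, start, end (+ name when present), sorted.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_intervals(gr)
}

#' Write an interval tibble to BED
#'
#' @param x Tibble with chrom, start, end (0-based half-open), optional name.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  gr <- intervals_to_granges(x)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a variant catalog TSV
#'
#' Expected columns: `chrom`, `pos` (1-based on disk, converted to 0-based in
#' memory), `anc`, `der` (single A/C/G/T nucleotides), `freq` (derived-allele
#' frequency in \[0, 1\]) and `archaic_state` (`ancestral`, `derived` or
#' `missing`).
#'
#' @param path TSV path.
#' @return Validated tibble with 0-based `pos`.
#' @export
read_variants <- function(path) {
  v <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         anc = readr::col_character(),
                         der = readr::col_character(),
                         freq = readr::col_double(),
                         archaic_state = readr::col_character()
                       ))
  validate_variants(dplyr::mutate(v, pos = .data$pos - 1L))
}

#' Write a variant catalog TSV (positions emitted 1-based)
#' @param variants Variant tibble with 0-based `pos`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(dplyr::mutate(variants, pos = .data$pos + 1L), path)
  invisible(path)
}

validate_variants <- function(v) {
  bases <- c("A", "C", "G", "T")
  if (!all(v$anc %in% bases) || !all(v$der %in% bases)) {
    abort("variant alleles must be single nucleotides in {A,C,G,T}.")
  }
  if (any(v$anc == v$der)) abort("ancestral and derived alleles must differ.")
  if (any(v$freq < 0 | v$freq > 1)) abort("derived-allele frequency must be in [0, 1].")
  ok_states <- c("ancestral", "derived", "missing")
  if (!all(v$archaic_state %in% ok_states)) {
    abort("archaic_state must be one of ancestral/derived/missing.")
  }
  v
}
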