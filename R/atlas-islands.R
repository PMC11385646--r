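#' Build a cross-dataset open-chromatin peak atlas
#'
#' Retains each autosomal reference peak whose length is covered at least
#' `min_frac` by the (merged) intervals of at least one support set, and
#' appends sex-chromosome intervals from dedicated sources verbatim (the
#' reference assay lacks chrX/chrY signal), flagged as such.
#'
#' @param reference Interval tibble of reference peaks (0-based half-open).
#' @param supports List of interval tibbles of supporting open-chromatin
#'   signal sets.
#' @param min_frac Minimum covered fraction (default 0.5, in (0, 1\]).
#' @param sex_chrom_sources Optional list of interval tibbles whose intervals
#'   are added verbatim.
#' @return A tibble of class `peak_atlas`: `chrom`, `start`, `end`,
#'   `supported_by` (comma-separated support-set indices), `sex_chrom_added`.
#' @export
build_peak_atlas <- function(reference, supports, min_frac = 0.5,
                             sex_chrom_sources = list()) {
  if (nrow(reference) == 0) abort("reference peak set is empty.")
  if (min_frac <= 0 || min_frac > 1) abort("min_frac must be in (0, 1].")
  ref_gr <- intervals_to_granges(reference)
  width <- GenomicRanges::width(ref_gr)
  support_names <- names(supports) %||% paste0("support", seq_along(supports))

  covered_by <- matrix(FALSE, nrow(reference), length(supports))
  for (s in seq_along(supports)) {
    sup_gr <- GenomicRanges::reduce(intervals_to_granges(supports[[s]]))
    hits <- GenomicRanges::findOverlaps(ref_gr, sup_gr)
    if (length(hits) == 0) next
    ov <- GenomicRanges::pintersect(
      ref_gr[S4Vectors::queryHits(hits)], sup_gr[S4Vectors::subjectHits(hits)]
    )
    cov <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(cov))
    covered_by[idx, s] <- as.numeric(cov) / width[idx] >= min_frac
  }
  keep <- rowSums(covered_by) > 0
  retained <- reference[keep, c("chrom", "start", "end")]
  retained$supported_by <- apply(
    covered_by[keep, , drop = FALSE], 1,
    function(z) paste(support_names[z], collapse = ",")
  )
  retained$sex_chrom_added <- FALSE

  extra <- purrr::imap_dfr(sex_chrom_sources, function(src, nm) {
    if (nrow(src) == 0) return(NULL)
    tibble(chrom = src$chrom, start = src$start, end = src$end,
           supported_by = as.character(nm), sex_chrom_added = TRUE)
  })
  atlas <- dplyr::bind_rows(retained, extra) |>
    dplyr::arrange(.data$chrom, .data$start)
  class(atlas) <- c("peak_atlas", class(atlas))
  atlas
}

#' Call regulatory islands from a derived-variant catalog
#'
#' A variant qualifies when (i) its derived-allele frequency is at least
#' `af_threshold`, (ii) archaic genomes carry the ancestral allele, (iii) it
#' lies inside an atlas peak, (iv) its centered window
#' `[pos - window/2, pos + window/2)` lies fully within the chromosome and
#' (v) that window contains no archaic lineage-specific derived position.
#' Overlapping qualifying windows are merged into a single island (hence "at
#' least" `window` bp), pooling member variants.
#'
#' @param variants Variant tibble (0-based `pos`, columns as
#'   [read_variants()]).
#' @param archaic_derived Archaic lineage-specific derived positions: tibble
#'   chrom/pos, or an interval tibble.
#' @param atlas Peak atlas (interval tibble, e.g. from [build_peak_atlas()]).
#' @param af_threshold Inclusive high-frequency cutoff (default 0.9).
#' @param window Window size in bp (default 3000, must be even).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A tibble of class `regulatory_islands`: `chrom`, `start`, `end`,
#'   `width`, `n_variants`, `variants` (list of member 0-based positions).
#' @export
call_regulatory_islands <- function(variants, archaic_derived, atlas,
                                    af_threshold = 0.9, window = 3000L,
                                    chrom_sizes) {
  if (af_threshold < 0 || af_threshold > 1) {
    abort("af_threshold must be in [0, 1].")
  }
  if (window %% 2 != 0) abort("window must be even.")
  validate_variants(variants)
  half <- as.integer(window) %/% 2L

  unknown <- !variants$chrom %in% names(chrom_sizes)
  if (any(unknown)) {
    inform(sprintf("skipping %d variant(s) on unknown chromosomes.", sum(unknown)))
    variants <- variants[!unknown, , drop = FALSE]
  }
  n_missing <- sum(variants$archaic_state == "missing")
  if (n_missing > 0) {
    inform(sprintf(
      "%d variant(s) with missing archaic genotype treated as non-qualifying.",
      n_missing
    ))
  }

  cand <- variants[variants$freq >= af_threshold &
                     variants$archaic_state == "ancestral", , drop = FALSE]
  if (nrow(cand) > 0) {
    ## inside an atlas peak
    v_gr <- GenomicRanges::GRanges(cand$chrom,
                                   IRanges::IRanges(cand$pos + 1L, cand$pos + 1L))
    in_peak <- GenomicRanges::countOverlaps(
      v_gr, intervals_to_granges(atlas[, c("chrom", "start", "end")])
    ) > 0
    ## window fully inside the chromosome
    size <- unname(chrom_sizes[cand$chrom])
    fits <- cand$pos - half >= 0 & cand$pos + half <= size
    ## window clean of archaic lineage-specific derived positions
    arch <- archaic_positions(archaic_derived)
    arch_gr <- if (length(arch) > 0) {
      av <- dplyr::bind_rows(purrr::imap(arch, function(d, ch) {
        tibble(chrom = ch, start = d$start, end = d$end)
      }))
      intervals_to_granges(av)
    } else GenomicRanges::GRanges()
    w_gr <- GenomicRanges::GRanges(
      cand$chrom, IRanges::IRanges(cand$pos - half + 1L, cand$pos + half)
    )
    clean <- GenomicRanges::countOverlaps(w_gr, arch_gr) == 0
    cand <- cand[in_peak & fits & clean, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    out <- tibble(chrom = character(0), start = integer(0), end = integer(0),
                  width = integer(0), n_variants = integer(0), variants = list())
    class(out) <- c("regulatory_islands", class(out))
    return(out)
  }
  win <- GenomicRanges::GRanges(
    cand$chrom, IRanges::IRanges(cand$pos - half + 1L, cand$pos + half)
  )
  merged <- GenomicRanges::reduce(win)
  hit <- GenomicRanges::findOverlaps(win, merged)
  members <- split(cand$pos[S4Vectors::queryHits(hit)],
                   S4Vectors::subjectHits(hit))
  out <- granges_to_intervals(merged)
  # granges_to_intervals sorts by chrom/start; align member lists the same way
  key_merged <- paste(as.character(GenomicRanges::seqnames(merged)),
                      GenomicRanges::start(merged) - 1L)
  key_out <- paste(out$chrom, out$start)
  members_aligned <- members[match(key_out, key_merged[as.integer(names(members))])]
  out$width <- out$end - out$start
  out$n_variants <- vapply(members_aligned, length, integer(1))
  out$variants <- lapply(members_aligned, function(p) sort(unname(p)))
  class(out) <- c("regulatory_islands", class(out))
  out
}

#' Link regulatory islands to genes through GREAT-style regulatory domains
#'
#' Each gene receives a basal domain around its TSS (`basal_up` upstream,
#' `basal_down` downstream, strand-aware) extended in both directions up to
#' the nearest neighboring basal domain and at most `extension` bp, clipped
#' to the chromosome. An island is linked to every gene whose regulatory
#' domain it overlaps. Curated domains, when supplied, replace the derived
#' domain for their genes.
#'
#' @param islands Island tibble (`chrom`, `start`, `end`).
#' @param tss_table Tibble with `gene`, `chrom`, `position` (0-based TSS) and
#'   `strand` (`+`/`-`; unknown values are treated as `+` with a message).
#' @param basal_up,basal_down Basal domain extents in bp (defaults 5000/1000).
#' @param extension Maximum extension in bp (default 1e6).
#' @param chrom_sizes Optional named vector to clip domains.
#' @param curated_domains Optional interval tibble with a `gene` column that
#'   overrides the derived domain for those genes.
#' @return Tibble `island_id` (chrom:start-end), `chrom`, `start`, `end`,
#'   `gene`; zero rows for islands in gene deserts.
#' @export
link_islands_to_genes <- function(islands, tss_table, basal_up = 5000L,
                                  basal_down = 1000L, extension = 1000000L,
                                  chrom_sizes = NULL, curated_domains = NULL) {
  domains <- regulatory_domains(tss_table, basal_up, basal_down, extension,
                                chrom_sizes)
  if (!is.null(curated_domains)) {
    domains <- dplyr::bind_rows(
      domains[!domains$gene %in% curated_domains$gene, ],
      curated_domains[, c("gene", "chrom", "start", "end")]
    )
  }
  if (nrow(islands) == 0) {
    return(tibble(island_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), gene = character(0)))
  }
  isl_gr <- intervals_to_granges(islands[, c("chrom", "start", "end")])
  dom_gr <- intervals_to_granges(domains[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(isl_gr, dom_gr)
  qi <- S4Vectors::queryHits(hits)
  tibble(
    island_id = sprintf("%s:%d-%d", islands$chrom[qi], islands$start[qi],
                        islands$end[qi]),
    chrom = islands$chrom[qi],
    start = islands$start[qi],
    end = islands$end[qi],
    gene = domains$gene[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene)
}

#' GREAT-style regulatory domains from a TSS table
#'
#' @inheritParams link_islands_to_genes
#' @return Tibble `gene`, `chrom`, `start`, `end` (0-based half-open).
#' @export
regulatory_domains <- function(tss_table, basal_up = 5000L, basal_down = 1000L,
                               extension = 1000000L, chrom_sizes = NULL) {
  tss <- as_tibble(tss_table)
  bad <- !tss$strand %in% c("+", "-")
  if (any(bad)) {
    inform(sprintf("%d gene(s) with unknown strand treated as '+'.", sum(bad)))
    tss$strand[bad] <- "+"
  }
  tss$basal_start <- as.numeric(ifelse(tss$strand == "+",
                                       tss$position - basal_up,
                                       tss$position - basal_down))
  tss$basal_end <- as.numeric(ifelse(tss$strand == "+",
                                     tss$position + basal_down,
                                     tss$position + basal_up))
  tss$basal_start <- pmax(tss$basal_start, 0)
  if (!is.null(chrom_sizes)) {
    tss$basal_end <- pmin(tss$basal_end, unname(chrom_sizes[tss$chrom]))
  }
  tss <- dplyr::arrange(tss, .data$chrom, .data$position)
  out <- tss |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      prev_end = dplyr::lag(cummax(.data$basal_end), default = -Inf),
      next_start = rev(cummin(rev(dplyr::lead(.data$basal_start, default = Inf)))),
      start = pmax(.data$basal_start - extension,
                   pmin(.data$basal_start, .data$prev_end),
                   0),
      end = pmin(.data$basal_end + extension,
                 pmax(.data$basal_end, .data$next_start))
    ) |>
    dplyr::ungroup()
  if (!is.null(chrom_sizes)) {
    out$end <- pmin(out$end, unname(chrom_sizes[out$chrom]))
  }
  tibble(gene = out$gene, chrom = out$chrom,
         start = as.integer(out$start), end = as.integer(out$end))
}

#' Fraction of module genes linked to at least one regulatory island
#'
#' @param assignment A [assign_gene_modules()] result.
#' @param island_gene_links Output of [link_islands_to_genes()].
#' @return Tibble `program`, `n_genes`, `n_linked`, `fraction`.
#' @export
module_island_fraction <- function(assignment, island_gene_links) {
  linked <- unique(island_gene_links$gene)
  members <- module_members(assignment)
  progs <- sort(unique(assignment$program))
  purrr::map_dfr(progs, function(p) {
    g <- members[[p]] %||% character(0)
    if (length(g) == 0) {
      warn(sprintf("module %s is empty; fraction 0.", p))
      return(tibble(program = p, n_genes = 0L, n_linked = 0L, fraction = 0))
    }
    tibble(program = p, n_genes = length(g),
           n_linked = sum(g %in% linked),
           fraction = mean(g %in% linked))
  })
}
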