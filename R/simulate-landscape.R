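#' Simulate a toy regulatory landscape with planted regulatory islands
#'
#' Generates a small genome with open-chromatin peaks, modern-human variant
#' records (derived-allele frequencies drawn so a known subset passes the
#' high-frequency filter, plus archaic-state flags), scattered archaic
#' lineage-specific derived positions, and the exact truth set of regulatory
#' islands implied by the island definition. The truth set is computed by an
#' internal brute-force scan ([brute_force_islands()]) that is independent of
#' the island caller.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param n_peaks Number of open-chromatin peaks (placed uniformly, width
#'   ~ 300-800 bp).
#' @param n_variants Number of modern variant records; 70% are placed inside
#'   peaks so qualifying variants exist.
#' @param frac_high_freq Fraction of variants drawn with derived-allele
#'   frequency >= 0.9 (the rest fall below).
#' @param frac_archaic_ancestral Fraction of variants at which archaics carry
#'   the ancestral allele (the rest split between derived and missing).
#' @param archaic_derived_density Per-bp Poisson density of archaic
#'   lineage-specific derived positions.
#' @param window Island window size in bp (default 3000).
#' @param af_threshold High-frequency cutoff (default 0.9).
#' @param seed Integer seed.
#' @return A list of class `toy_regulatory_landscape`: `chrom_sizes`, `peaks`
#'   (interval tibble), `variants` (0-based tibble), `archaic_derived`
#'   (position tibble chrom/pos), `truth_islands` (interval tibble with
#'   member-variant list column; may be empty), `params`.
#' @export
simulate_regulatory_landscape <- function(chrom_sizes = c(chr1 = 200000L, chr2 = 150000L),
                                          n_peaks = 40, n_variants = 120,
                                          frac_high_freq = 0.5,
                                          frac_archaic_ancestral = 0.7,
                                          archaic_derived_density = 1e-4,
                                          window = 3000L, af_threshold = 0.9,
                                          seed = 1L) {
  if (any(chrom_sizes <= 0) || n_peaks < 1 || n_variants < 1) {
    abort("chromosome sizes and counts must be positive.")
  }
  if (frac_high_freq < 0 || frac_high_freq > 1 ||
      frac_archaic_ancestral < 0 || frac_archaic_ancestral > 1) {
    abort("fractions must be in [0, 1].")
  }
  set.seed(seed)
  chroms <- names(chrom_sizes)
  if (min(chrom_sizes) < window) {
    warn("a chromosome is shorter than the island window; no clean window fits there.")
  }

  ## peaks: uniform placement proportional to chromosome length, merged
  p_chrom <- sample(chroms, n_peaks, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
  width <- sample(300:800, n_peaks, replace = TRUE)
  p_start <- vapply(seq_len(n_peaks), function(i) {
    as.integer(floor(runif(1, 0, chrom_sizes[p_chrom[i]] - width[i])))
  }, integer(1))
  peaks <- tibble(chrom = p_chrom, start = p_start, end = p_start + width) |>
    intervals_to_granges() |>
    GenomicRanges::reduce() |>
    granges_to_intervals()

  ## variants: 70% inside peaks, frequencies split around the threshold
  n_in <- round(0.7 * n_variants)
  in_peak_idx <- sample.int(nrow(peaks), n_in, replace = TRUE)
  pos_in <- floor(runif(n_in, peaks$start[in_peak_idx], peaks$end[in_peak_idx]))
  chrom_in <- peaks$chrom[in_peak_idx]
  n_out <- n_variants - n_in
  chrom_out <- sample(chroms, n_out, replace = TRUE,
                      prob = chrom_sizes / sum(chrom_sizes))
  pos_out <- vapply(chrom_out, function(ch) {
    as.integer(floor(runif(1, 0, chrom_sizes[ch])))
  }, integer(1))
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, n_variants, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(bases, a), 1), character(1))
  hi <- runif(n_variants) < frac_high_freq
  freq <- ifelse(hi, runif(n_variants, af_threshold, 1),
                 runif(n_variants, 0, af_threshold - 1e-9))
  state <- ifelse(runif(n_variants) < frac_archaic_ancestral, "ancestral",
                  sample(c("derived", "missing"), n_variants, replace = TRUE))
  variants <- tibble(
    chrom = c(chrom_in, chrom_out),
    pos = as.integer(c(pos_in, pos_out)),
    anc = anc, der = der, freq = freq, archaic_state = state
  ) |>
    dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos)

  ## archaic lineage-specific derived positions: Poisson per chromosome
  archaic_derived <- purrr::map_dfr(chroms, function(ch) {
    k <- rpois(1, archaic_derived_density * chrom_sizes[ch])
    if (k == 0) return(tibble(chrom = character(0), pos = integer(0)))
    tibble(chrom = ch, pos = sort(as.integer(floor(runif(k, 0, chrom_sizes[ch])))))
  })

  truth <- brute_force_islands(variants, archaic_derived, peaks,
                               af_threshold = af_threshold, window = window,
                               chrom_sizes = chrom_sizes)
  if (nrow(truth) == 0) {
    warn("no regulatory island is feasible under these densities; empty truth set.")
  }
  structure(
    list(chrom_sizes = chrom_sizes, peaks = peaks, variants = variants,
         archaic_derived = archaic_derived, truth_islands = truth,
         params = list(n_peaks = n_peaks, n_variants = n_variants,
                       frac_high_freq = frac_high_freq,
                       frac_archaic_ancestral = frac_archaic_ancestral,
                       archaic_derived_density = archaic_derived_density,
                       window = window, af_threshold = af_threshold,
                       seed = seed)),
    class = "toy_regulatory_landscape"
  )
}

#' Brute-force regulatory-island truth scan
#'
#' Reference implementation of the island definition by direct per-variant
#' checks and linear scans (no interval-tree machinery): a variant qualifies
#' when its derived-allele frequency passes the threshold, archaics carry the
#' ancestral allele, it lies inside a peak, and its centered window fits the
#' chromosome and contains no archaic lineage-specific derived position;
#' overlapping qualifying windows are merged. Kept deliberately independent
#' of [call_regulatory_islands()] so either can audit the other.
#'
#' @param variants Variant tibble (0-based `pos`).
#' @param archaic_derived Tibble chrom/pos of archaic derived positions (or
#'   interval tibble with start/end).
#' @param peaks Interval tibble of open-chromatin peaks.
#' @param af_threshold,window,chrom_sizes Island-definition parameters.
#' @return Interval tibble `chrom`, `start`, `end` with a `variants` list
#'   column of member 0-based positions.
#' @export
brute_force_islands <- function(variants, archaic_derived, peaks,
                                af_threshold = 0.9, window = 3000L,
                                chrom_sizes) {
  half <- window %/% 2L
  arch_pos <- archaic_positions(archaic_derived)
  qual <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$freq < af_threshold) next
    if (!identical(v$archaic_state, "ancestral")) next
    if (!v$chrom %in% names(chrom_sizes)) next
    in_peak <- FALSE
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] == v$chrom &&
          v$pos >= peaks$start[j] && v$pos < peaks$end[j]) {
        in_peak <- TRUE
        break
      }
    }
    if (!in_peak) next
    w0 <- v$pos - half
    w1 <- v$pos + half
    if (w0 < 0 || w1 > chrom_sizes[[v$chrom]]) next
    ap <- arch_pos[[v$chrom]]
    clean <- TRUE
    if (!is.null(ap) && nrow(ap) > 0) {
      for (j in seq_len(nrow(ap))) {
        if (ap$start[j] < w1 && ap$end[j] > w0) { clean <- FALSE; break }
      }
    }
    qual[i] <- clean
  }
  qv <- variants[qual, , drop = FALSE]
  if (nrow(qv) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  variants = list()))
  }
  wins <- tibble(chrom = qv$chrom, start = qv$pos - half, end = qv$pos + half,
                 vpos = qv$pos) |>
    dplyr::arrange(.data$chrom, .data$start)
  out <- list()
  cur <- wins[1, ]
  members <- cur$vpos
  for (i in seq_len(nrow(wins))[-1]) {
    w <- wins[i, ]
    if (w$chrom == cur$chrom && w$start < cur$end) {
      cur$end <- max(cur$end, w$end)
      members <- c(members, w$vpos)
    } else {
      out[[length(out) + 1]] <- tibble(chrom = cur$chrom, start = cur$start,
                                       end = cur$end, variants = list(members))
      cur <- w
      members <- w$vpos
    }
  }
  out[[length(out) + 1]] <- tibble(chrom = cur$chrom, start = cur$start,
                                   end = cur$end, variants = list(members))
  dplyr::bind_rows(out)
}

# Normalize archaic-derived input (position list or interval set) to a list
# of per-chromosome interval tibbles; positions become width-1 intervals.
archaic_positions <- function(archaic_derived) {
  if (is.null(archaic_derived) || nrow(archaic_derived) == 0) return(list())
  iv <- if ("pos" %in% names(archaic_derived)) {
    tibble(chrom = archaic_derived$chrom,
           start = archaic_derived$pos, end = archaic_derived$pos + 1L)
  } else {
    archaic_derived[, c("chrom", "start", "end")]
  }
  split(iv[, c("start", "end")], iv$chrom)
}
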