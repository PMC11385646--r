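## Fast any-overlap counting against a merged, sorted target set: a query
## [s, e) overlaps some target iff more targets start before e than end at or
## before s. Vectorized over queries via findInterval.
overlap_index <- function(target) {
  tg <- GenomicRanges::reduce(intervals_to_granges(target))
  iv <- granges_to_intervals(tg)
  split(iv[, c("start", "end")], iv$chrom)
}

count_overlapping <- function(chrom, start, end, index) {
  n_ov <- 0L
  for (ch in unique(chrom)) {
    tgt <- index[[ch]]
    sel <- chrom == ch
    if (is.null(tgt) || nrow(tgt) == 0) next
    n_start_before <- findInterval(end[sel] - 0.5, tgt$start)
    n_end_at_or_before <- findInterval(start[sel] + 0.5, tgt$end)
    n_ov <- n_ov + sum(n_start_before > n_end_at_or_before)
  }
  n_ov
}

#' Permutation test for regional overlap enrichment
#'
#' The observed statistic is the number of query regions overlapping at least
#' one target region. Each permutation redraws regions of identical lengths
#' on the same chromosomes, uniformly at random (overlaps among placed
#' regions allowed; optional exclusion mask rejected by redraw). The
#' empirical p-value uses the +1 correction,
#' `p = (1 + #[null as or more extreme]) / (1 + n_perm)`, so p is always
#' positive.
#'
#' @param query Interval tibble of query regions.
#' @param target Interval tibble of target regions.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param alternative `"greater"`, `"less"` or `"two-sided"`.
#' @param mask Optional interval tibble; redrawn regions overlapping the mask
#'   are rejected and redrawn (up to 100 attempts each).
#' @return Object of class `perm_test`: `observed`, `null_mean`, `null_sd`,
#'   `n_perm`, `p.value`, `z`, `alternative`, `seed`, `null_values`.
#' @export
permutation_enrichment <- function(query, target, chrom_sizes, n_perm = 10000,
                                   seed = 1L,
                                   alternative = c("greater", "less", "two-sided"),
                                   mask = NULL) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) abort("n_perm must be >= 1.")
  lens <- query$end - query$start
  sizes <- unname(chrom_sizes[query$chrom])
  if (anyNA(sizes)) abort("query on a chromosome absent from chrom_sizes.")
  if (any(lens > sizes)) abort("a query region is longer than its chromosome.")
  idx <- overlap_index(target)
  mask_idx <- if (!is.null(mask) && nrow(mask) > 0) overlap_index(mask) else NULL

  observed <- count_overlapping(query$chrom, query$start, query$end, idx)

  set.seed(as.integer(seed))
  nq <- nrow(query)
  null_values <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    starts <- floor(runif(nq) * (sizes - lens + 1))
    if (!is.null(mask_idx)) {
      for (attempt in 1:100) {
        bad <- vapply(seq_len(nq), function(i) {
          count_overlapping(query$chrom[i], starts[i], starts[i] + lens[i],
                            mask_idx) > 0
        }, logical(1))
        if (!any(bad)) break
        starts[bad] <- floor(runif(sum(bad)) * (sizes[bad] - lens[bad] + 1))
      }
    }
    null_values[b] <- count_overlapping(query$chrom, starts, starts + lens, idx)
  }
  p_greater <- (1 + sum(null_values >= observed)) / (1 + n_perm)
  p_less <- (1 + sum(null_values <= observed)) / (1 + n_perm)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              `two-sided` = min(1, 2 * min(p_greater, p_less)))
  nsd <- sd(null_values)
  structure(
    list(observed = observed,
         null_mean = mean(null_values),
         null_sd = nsd,
         n_perm = as.integer(n_perm),
         p.value = p,
         z = if (isTRUE(nsd > 0)) (observed - mean(null_values)) / nsd else NA_real_,
         alternative = alternative,
         seed = as.integer(seed),
         null_values = null_values),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> observed %d vs null %.2f +/- %.2f (%d perms); p = %.4g (%s)\n",
    x$observed, x$null_mean, x$null_sd, x$n_perm, x$p.value, x$alternative
  ))
  invisible(x)
}
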