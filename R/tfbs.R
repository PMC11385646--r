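#' Score allele-specific binding-affinity effects of a variant
#'
#' For every motif, all offsets covering the variant position are scanned on
#' both strands for the ancestral (ref) and derived (alt) allele; the single
#' (offset, strand) maximizing the better allele's scaled score is kept per
#' motif. An effect is emitted when the better allele's exact match p-value
#' is at or below `p_threshold`. Across all emitted motif x variant tests the
#' p-values are Benjamini-Hochberg adjusted, and per TF only the single best
#' effect per variant is kept (redundant motifs of the same factor dropped).
#'
#' @param variants Variant tibble (0-based `pos`; `anc` is the reference
#'   context allele, `der` the derived allele).
#' @param context Named character vector or list mapping a variant id
#'   (`chrom:pos`) to a list with `seq` (context sequence, ACGT) and
#'   `var_offset` (1-based position of the variant within `seq`). The
#'   context must span at least motif-length - 1 bases on each side.
#' @param pwms List of `pwm_record` objects.
#' @param p_threshold Match p-value threshold (default 1e-4).
#' @param background Base composition for [match_pvalue()] (default uniform).
#' @return A tibble of class `tfbs_effects`: `variant_id`, `motif`, `tf`,
#'   `strand`, `offset` (0-based start of the motif window relative to the
#'   variant), `ref_score`, `alt_score`, `delta`, `p.value`, `q.value`.
#' @export
evaluate_variant <- function(variants, context, pwms, p_threshold = 1e-4,
                             background = rep(0.25, 4)) {
  validate_variants(variants)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    vid <- sprintf("%s:%d", v$chrom, v$pos)
    ctx <- context[[vid]]
    if (is.null(ctx)) abort(sprintf("no context sequence for variant %s.", vid))
    seq <- toupper(ctx$seq)
    off <- ctx$var_offset
    if (substr(seq, off, off) != v$anc) {
      abort(sprintf(
        "context for %s carries '%s' at the variant position, expected ancestral '%s'.",
        vid, substr(seq, off, off), v$anc
      ))
    }
    alt_seq <- seq
    substr(alt_seq, off, off) <- v$der
    for (pw in pwms) {
      L <- nrow(pw$matrix)
      starts <- (off - L + 1):off
      if (min(starts) < 1 || max(starts) + L - 1 > nchar(seq)) {
        abort(sprintf(
          "context for %s too short for motif %s (length %d).", vid, pw$id, L
        ))
      }
      pw_rc <- revcomp_pwm(pw)
      best <- NULL
      for (s in starts) {
        ref_k <- substr(seq, s, s + L - 1)
        alt_k <- substr(alt_seq, s, s + L - 1)
        for (strand in c("+", "-")) {
          p_use <- if (strand == "+") pw else pw_rc
          rs <- score_sequence(p_use, ref_k)
          as_ <- score_sequence(p_use, alt_k)
          key <- max(rs, as_)
          if (is.null(best) || key > best$key) {
            best <- list(key = key, strand = strand, start = s,
                         ref = rs, alt = as_)
          }
        }
      }
      pv <- match_pvalue(if (best$strand == "+") pw else pw_rc, best$key,
                         background = background)
      if (pv <= p_threshold) {
        rows[[length(rows) + 1]] <- tibble(
          variant_id = vid, motif = pw$id, tf = pw$tf,
          strand = best$strand, offset = best$start - off,
          ref_score = best$ref, alt_score = best$alt,
          delta = best$alt - best$ref, p.value = pv
        )
      }
    }
  }
  if (length(rows) == 0) {
    out <- tibble(variant_id = character(0), motif = character(0),
                  tf = character(0), strand = character(0), offset = integer(0),
                  ref_score = numeric(0), alt_score = numeric(0),
                  delta = numeric(0), p.value = numeric(0), q.value = numeric(0))
    class(out) <- c("tfbs_effects", class(out))
    return(out)
  }
  out <- dplyr::bind_rows(rows)
  out$q.value <- p.adjust(out$p.value, method = "BH")
  ## one best effect per TF x variant: best-matching allele, then |delta|
  out <- out |>
    dplyr::group_by(.data$variant_id, .data$tf) |>
    dplyr::arrange(dplyr::desc(pmax(.data$ref_score, .data$alt_score)),
                   dplyr::desc(abs(.data$delta)), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$variant_id, .data$tf)
  class(out) <- c("tfbs_effects", class(out))
  out
}

#' Classify per-TF binding-affinity effects
#'
#' An effect is `strong` when its absolute affinity difference falls in the
#' fourth (top) quartile of the |delta| distribution over all effects. Per
#' TF, the class is `increased` if all strong effects raise affinity,
#' `reduced` if all lower it, `both` if mixed, and `none` without strong
#' effects; the frequency score is strong hits / total hits.
#'
#' @param effects A [evaluate_variant()] result (>= 1 row).
#' @return Tibble `tf`, `n_total`, `n_strong`, `n_strong_up`,
#'   `n_strong_down`, `class`, `frequency_score`.
#' @export
classify_tf_effects <- function(effects) {
  if (nrow(effects) == 0) abort("need at least one effect to classify.")
  thr <- quantile(abs(effects$delta), 0.75, names = FALSE)
  effects$strength <- ifelse(abs(effects$delta) >= thr, "strong", "weak")
  effects |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_strong = sum(.data$strength == "strong"),
      n_strong_up = sum(.data$strength == "strong" & .data$delta > 0),
      n_strong_down = sum(.data$strength == "strong" & .data$delta < 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      class = dplyr::case_when(
        n_strong == 0 ~ "none",
        n_strong_up > 0 & n_strong_down > 0 ~ "both",
        n_strong_up > 0 ~ "increased",
        TRUE ~ "reduced"
      ),
      frequency_score = .data$n_strong / .data$n_total
    )
}

#' Add the strong/weak strength flag to an effects table
#'
#' @inheritParams classify_tf_effects
#' @return The effects tibble with a `strength` column (`strong` iff |delta|
#'   is at or above the 75th percentile of |delta| over all effects).
#' @export
effect_strength <- function(effects) {
  thr <- quantile(abs(effects$delta), 0.75, names = FALSE)
  dplyr::mutate(effects,
                strength = ifelse(abs(.data$delta) >= thr, "strong", "weak"))
}
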