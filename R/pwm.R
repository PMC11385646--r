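#' Parse a JASPAR/HOCOMOCO-style motif collection
#'
#' Accepts count or frequency matrices in the common 4-row text layout:
#' a header line `>motif_id TF_NAME` followed by four rows, either bare
#' numbers or `A [ 1 2 3 ]` style. Each position is pseudocount-regularized
#' (total pseudocount split evenly across the four bases) and normalized to
#' probabilities.
#'
#' @param text Character vector of lines, or a single string with newlines,
#'   or a file path.
#' @param pseudocount Total pseudocount added per position (default 0.8,
#'   i.e. 0.2 per base).
#' @return List of `pwm_record` objects: `id`, `tf`, `matrix` (L x 4
#'   probability matrix, columns A/C/G/T, rows summing to 1).
#' @export
parse_pwms <- function(text, pseudocount = 0.8) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readr::read_lines(text)
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    warn("empty motif collection.")
    return(list())
  }
  headers <- grep("^>", lines)
  if (length(headers) == 0) abort("no motif headers ('>id name') found.")
  bounds <- c(headers, length(lines) + 1L)
  purrr::map(seq_along(headers), function(i) {
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    id <- parts[1]
    tf <- if (length(parts) > 1) parts[2] else parts[1]
    body <- lines[(headers[i] + 1):(bounds[i + 1] - 1)]
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", " ", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      vals[!is.na(vals)]
    })
    rows <- rows[vapply(rows, length, integer(1)) > 0]
    if (length(rows) != 4 || length(unique(vapply(rows, length, integer(1)))) != 1) {
      abort(sprintf("motif %s: expected a rectangular 4-row matrix.", id))
    }
    counts <- t(do.call(rbind, rows))              # L x 4
    colnames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) abort(sprintf("motif %s: negative entries.", id))
    prob <- (counts + pseudocount / 4) / (rowSums(counts) + pseudocount)
    structure(list(id = id, tf = tf, matrix = prob), class = "pwm_record")
  })
}

#' @export
print.pwm_record <- function(x, ...) {
  cat(sprintf("<pwm_record> %s (%s), length %d\n", x$id, x$tf, nrow(x$matrix)))
  invisible(x)
}

#' Write motifs back to JASPAR-style text
#' @param pwms List of `pwm_record` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pwms <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste(">", p$id, p$tf),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, " [ ", paste(format(p$matrix[, b], digits = 10), collapse = " "), " ]")
      }, character(1)))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

base_index <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) abort("sequence contains an ambiguous base.")
  idx
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "")[[1]]), collapse = "")
}

# Reverse-complement of a PWM: reverse positions, swap complementary columns.
revcomp_pwm <- function(pwm) {
  m <- pwm$matrix[rev(seq_len(nrow(pwm$matrix))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  pwm$matrix <- m
  pwm
}

#' Information-content match score of a sequence against a PWM
#'
#' The raw score is the sum over positions of the probability of the observed
#' base; it is min-max scaled so the consensus sequence (argmax base at every
#' position) scores 1 and the anti-consensus scores 0.
#'
#' @param pwm A `pwm_record`.
#' @param seq Character string of length `nrow(pwm$matrix)`, bases in ACGT.
#' @return Scaled score in \[0, 1\].
#' @export
score_sequence <- function(pwm, seq) {
  m <- pwm$matrix
  idx <- base_index(seq)
  if (length(idx) != nrow(m)) {
    abort(sprintf("sequence length %d != motif length %d.", length(idx), nrow(m)))
  }
  raw <- sum(m[cbind(seq_len(nrow(m)), idx)])
  lo <- sum(apply(m, 1, min))
  hi <- sum(apply(m, 1, max))
  if (hi - lo == 0) return(0)   # degenerate PWM: every sequence ties
  (raw - lo) / (hi - lo)
}

#' Exact tail p-value of a scaled PWM match score
#'
#' Computes `P(score of a random background L-mer >= scaled_score)` by
#' dynamic-programming convolution of the per-position score distributions on
#' a fixed grid. The user-facing grid bin is 1e-4 of the scaled \[0, 1\]
#' range; internally each position is discretized at bin/L so the accumulated
#' rounding error stays within one user-facing bin.
#'
#' @param pwm A `pwm_record`.
#' @param scaled_score Score in scaled units (values <= 0 give p = 1, values
#'   > 1 give p = 0).
#' @param background Base probabilities (A, C, G, T), summing to 1; default
#'   uniform.
#' @param bin Grid bin width on the scaled range (default 1e-4).
#' @return The tail probability.
#' @export
match_pvalue <- function(pwm, scaled_score, background = rep(0.25, 4),
                         bin = 1e-4) {
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1.")
  m <- pwm$matrix
  L <- nrow(m)
  if (scaled_score <= 0) return(1)
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  W <- sum(hi - lo)
  if (W == 0) return(1)         # degenerate PWM: all mass at score 0
  if (scaled_score > 1 + 1e-12) return(0)
  delta <- bin / L                               # per-position grid
  units <- round(((m - lo) / W) / delta)         # L x 4 integer contributions
  max_units <- sum(apply(units, 1, max))
  p <- numeric(max_units + 1)
  p[1] <- 1
  for (i in seq_len(L)) {
    pn <- numeric(max_units + 1)
    for (b in 1:4) {
      u <- units[i, b]
      n_keep <- max_units + 1 - u
      pn[(u + 1):(max_units + 1)] <- pn[(u + 1):(max_units + 1)] +
        background[b] * p[1:n_keep]
    }
    p <- pn
  }
  target <- round(scaled_score / delta)
  if (target > max_units) return(0)
  sum(p[(target + 1):(max_units + 1)])
}
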