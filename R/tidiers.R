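#' Tidy a factorization replicate into a long tibble
#'
#' @param x An `nmf_fit`.
#' @param matrix Which factor to tidy: `"A"` (cell x program temporal
#'   patterns) or `"X"` (program x gene coefficients).
#' @param ... Unused.
#' @return A long tibble (`cell`/`gene`, `program`, `value`).
#' @export
tidy.nmf_fit <- function(x, matrix = c("A", "X"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "A") {
    as_tibble(x$A, rownames = "cell") |>
      tidyr::pivot_longer(-"cell", names_to = "program", values_to = "value")
  } else {
    as_tibble(t(x$X), rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "program", values_to = "value")
  }
}

#' One-row summary of a factorization replicate
#' @param x An `nmf_fit`.
#' @param ... Unused.
#' @return Tibble with `mode`, `rank`, `objective`, `n_iter`, `converged`,
#'   `seed`.
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(mode = x$mode, rank = x$rank,
         objective = utils::tail(x$objective_trace, 1),
         n_iter = x$n_iter, converged = x$converged, seed = x$seed)
}

#' Tidy consensus activations into a long tibble
#' @param x An `nmf_consensus`.
#' @param ... Unused.
#' @return Tibble `cell`, `pseudotime`, `branch`, `program`, `activation`.
#' @export
tidy.nmf_consensus <- function(x, ...) {
  act <- as_tibble(x$activations, rownames = "cell")
  act$pseudotime <- x$cells$pseudotime
  act$branch <- x$cells$branch
  tidyr::pivot_longer(act, -c("cell", "pseudotime", "branch"),
                      names_to = "program", values_to = "activation")
}

#' One-row summary of a consensus result
#' @param x An `nmf_consensus`.
#' @param ... Unused.
#' @return Tibble with `mode`, `rank`, `silhouette`, `frobenius_error`.
#' @export
glance.nmf_consensus <- function(x, ...) {
  tibble(mode = x$mode, rank = x$rank, silhouette = x$silhouette,
         frobenius_error = x$frobenius_error)
}

#' Tidy a permutation test's null distribution
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return Tibble `permutation`, `overlap`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(permutation = seq_along(x$null_values), overlap = x$null_values)
}

#' One-row summary of a permutation test
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return Tibble `observed`, `null_mean`, `null_sd`, `z`, `p.value`,
#'   `n_perm`, `alternative`.
#' @export
glance.perm_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
         z = x$z, p.value = x$p.value, n_perm = x$n_perm,
         alternative = x$alternative)
}
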