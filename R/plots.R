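#' Plot consensus program activations along pseudotime
#'
#' One panel per program; each point is a cell colored by branch, showing
#' the sequential (and, for transient programs, bump-shaped) activation of
#' expression programs along the trajectory.
#'
#' @param object An `nmf_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmf_consensus <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$pseudotime, y = .data$activation,
                                 colour = .data$branch)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$program)) +
    ggplot2::labs(x = "pseudotime", y = "activation (0-1)") +
    ggplot2::theme_minimal()
}

#' Plot a permutation test's null distribution against the observed overlap
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_test <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "query regions overlapping target",
                  y = "permutations",
                  title = sprintf("observed = %d, p = %.3g (%s)",
                                  object$observed, object$p.value,
                                  object$alternative)) +
    ggplot2::theme_minimal()
}

#' Plot rank-sweep diagnostics
#'
#' Silhouette (stability) and Frobenius error against candidate rank, the
#' two measures guiding rank selection.
#'
#' @param sweep A [rank_sweep()] tibble.
#' @return A ggplot object.
#' @export
plot_rank_sweep <- function(sweep) {
  sweep |>
    tidyr::pivot_longer(c("silhouette", "frobenius_error"),
                        names_to = "measure", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::theme_minimal()
}
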