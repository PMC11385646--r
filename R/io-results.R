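#' Write a consensus result to disk
#'
#' Emits `consensus_A.tsv` (cell, pseudotime, branch, one column per
#' program), `consensus_X.tsv` (gene, one column per program) and
#' `consensus_diagnostics.json` (silhouette, Frobenius error, mode, rank,
#' config echo).
#'
#' @param consensus An `nmf_consensus`.
#' @param outdir Output directory (created if missing).
#' @param config Optional configuration list echoed into the JSON.
#' @return Invisibly, the paths written.
#' @export
write_consensus <- function(consensus, outdir, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  a_path <- file.path(outdir, "consensus_A.tsv")
  x_path <- file.path(outdir, "consensus_X.tsv")
  j_path <- file.path(outdir, "consensus_diagnostics.json")
  a_tab <- dplyr::bind_cols(
    consensus$cells[, c("cell_id", "pseudotime", "branch")],
    as_tibble(consensus$consensus_A)
  )
  readr::write_tsv(a_tab, a_path)
  readr::write_tsv(as_tibble(t(consensus$consensus_X), rownames = "gene"), x_path)
  diag <- list(
    mode = consensus$mode, rank = consensus$rank,
    silhouette = consensus$silhouette,
    frobenius_error = consensus$frobenius_error,
    config = config
  )
  jsonlite::write_json(diag, j_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(a_path, x_path, j_path))
}

#' Write a gene-module assignment table
#' @param assignment A [assign_gene_modules()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_module_assignment <- function(assignment, path) {
  readr::write_tsv(as_tibble(assignment), path)
  invisible(path)
}

#' Write a permutation-test result as JSON
#' @param x A `perm_test`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_perm_test <- function(x, path) {
  jsonlite::write_json(
    list(observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
         n_perm = x$n_perm, p_value = x$p.value, z = x$z,
         alternative = x$alternative, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
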