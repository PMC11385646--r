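#' Trajectory dataset: expression with per-cell pseudotime and branch
#'
#' Container for a non-negative genes x cells expression matrix (normalized
#' log expression) together with per-cell pseudotime and branch labels, the
#' input of the pseudotime-informed factorization. Pseudotime is any scalar
#' ordering of cells along a differentiation continuum produced upstream by
#' a trajectory-inference tool; this package never infers it.
#'
#' @param expr Numeric matrix, genes x cells, all values finite and >= 0.
#'   Row names are gene identifiers, column names cell identifiers (generated
#'   when absent).
#' @param cells Data frame with columns `cell_id`, `pseudotime` (finite
#'   numeric) and `branch` (character/factor), one row per column of `expr`.
#'
#' @return An object of class `trajectory_dataset`: a list with elements
#'   `expr` (genes x cells matrix), `cells` (tibble, aligned to the columns
#'   of `expr`) and `gene_ids`.
#' @export
trajectory_dataset <- function(expr, cells) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) abort("`expr` must be a numeric matrix.")
  if (anyNA(expr) || any(!is.finite(expr))) {
    abort("`expr` contains NA or non-finite values.")
  }
  if (any(expr < 0)) {
    bad <- which(expr < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "`expr` must be non-negative; first negative entry at [%d, %d].",
      bad[1], bad[2]
    ))
  }
  if (is.null(rownames(expr))) rownames(expr) <- paste0("gene", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- paste0("cell", seq_len(ncol(expr)))
  if (anyDuplicated(rownames(expr))) abort("gene identifiers must be unique.")
  if (anyDuplicated(colnames(expr))) abort("cell identifiers must be unique.")

  cells <- as_tibble(cells)
  need <- c("cell_id", "pseudotime", "branch")
  if (!all(need %in% names(cells))) {
    abort("`cells` must have columns cell_id, pseudotime, branch.")
  }
  if (anyDuplicated(cells$cell_id)) abort("duplicate cell_id in metadata.")
  missing_cells <- setdiff(colnames(expr), cells$cell_id)
  if (length(missing_cells) > 0) {
    abort(sprintf(
      "metadata missing %d cell(s): %s",
      length(missing_cells),
      paste(head(missing_cells, 5), collapse = ", ")
    ))
  }
  cells <- cells[match(colnames(expr), cells$cell_id), , drop = FALSE]
  if (anyNA(cells$pseudotime) || any(!is.finite(cells$pseudotime))) {
    abort("pseudotime must be finite for every cell.")
  }
  cells$branch <- as.character(cells$branch)

  structure(
    list(expr = expr, cells = cells, gene_ids = rownames(expr)),
    class = "trajectory_dataset"
  )
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf(
    "<trajectory_dataset> %d genes x %d cells; branches: %s\n",
    nrow(x$expr), ncol(x$expr),
    paste(sort(unique(x$cells$branch)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.trajectory_dataset <- function(x) dim(x$expr)

#' Subset a trajectory to one lineage (root cells plus one branch)
#'
#' Factorizations are fit per lineage: the shared root segment of a
#' bifurcating trajectory together with one post-bifurcation branch, mirroring
#' separate apical-to-basal analyses (e.g. vRG to oRG and vRG to IPC).
#'
#' @param data A [trajectory_dataset()].
#' @param branch Branch label to keep.
#' @param root Label of the shared pre-bifurcation segment (default "root";
#'   use `NULL` to keep only `branch` cells).
#' @return A `trajectory_dataset` restricted to the selected cells, ordered by
#'   pseudotime.
#' @export
subset_branch <- function(data, branch, root = "root") {
  stopifnot(inherits(data, "trajectory_dataset"))
  keep_labels <- c(branch, root)
  keep <- data$cells$branch %in% keep_labels
  if (!any(data$cells$branch == branch)) {
    abort(sprintf("no cells with branch label '%s'.", branch))
  }
  ord <- order(data$cells$pseudotime[keep])
  idx <- which(keep)[ord]
  trajectory_dataset(data$expr[, idx, drop = FALSE], data$cells[idx, ])
}

#' Read a trajectory dataset from disk
#'
#' Reads either a MatrixMarket sparse matrix plus gene/cell sidecar files, or
#' a dense TSV (genes x cells with a leading gene-id column), together with a
#' cell metadata TSV (`cell_id`, `pseudotime`, `branch`).
#'
#' @param expr_path Path to the expression matrix: `.mtx` (with sidecars
#'   `<stem>.genes.tsv` and `<stem>.cells.tsv`, one id per line) or a dense
#'   TSV.
#' @param meta_path Path to the cell metadata TSV.
#' @return A [trajectory_dataset()].
#' @export
load_trajectory <- function(expr_path, meta_path) {
  if (grepl("\\.mtx$", expr_path)) {
    m <- as.matrix(Matrix::readMM(expr_path))
    stem <- sub("\\.mtx$", "", expr_path)
    rownames(m) <- readr::read_lines(paste0(stem, ".genes.tsv"))
    colnames(m) <- readr::read_lines(paste0(stem, ".cells.tsv"))
  } else {
    tab <- readr::read_tsv(expr_path, show_col_types = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab[[1]]
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  trajectory_dataset(m, meta)
}

#' Write a trajectory dataset to disk
#'
#' Emits a MatrixMarket matrix (`<stem>.mtx`) with gene/cell id sidecars and a
#' metadata TSV (`<stem>.cells_meta.tsv`), the exact formats read back by
#' [load_trajectory()].
#'
#' @param data A [trajectory_dataset()].
#' @param stem Output path stem (no extension).
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(data, stem) {
  stopifnot(inherits(data, "trajectory_dataset"))
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(as(Matrix::Matrix(data$expr, sparse = TRUE), "generalMatrix"), mtx)
  readr::write_lines(rownames(data$expr), paste0(stem, ".genes.tsv"))
  readr::write_lines(colnames(data$expr), paste0(stem, ".cells.tsv"))
  meta <- paste0(stem, ".cells_meta.tsv")
  readr::write_tsv(data$cells, meta)
  invisible(c(mtx, meta))
}
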