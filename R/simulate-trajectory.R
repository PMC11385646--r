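## Planted temporal programs for one lineage. Program 1 declines from the
## root; program 2 is a transient bump near the bifurcation (the pattern a
## time-aware factorization should resolve better than a free one); later
## programs switch on sequentially, with branch-specific timing after the
## bifurcation point.
planted_patterns <- function(n_programs, branch = c("A", "B"),
                             bifurcation = 0.5) {
  branch <- match.arg(branch)
  shift <- if (branch == "A") 0 else 0.06
  ## programs tile pseudotime in roughly equal-power windows with sequential
  ## handoff: an early program that declines from the root, one transient
  ## bump near the bifurcation, intermediate windowed programs, and a
  ## terminal program that switches on last and stays on
  ## transition widths are kept broad enough that every pattern lies close
  ## to the non-negative cubic-spline cone of the default basis (4 interior
  ## knots), as befits global expression trends
  pats <- list(
    function(t) 1 / (1 + exp((t - 0.22) / 0.08)),
    function(t) exp(-(t - 0.42)^2 / (2 * 0.16^2))
  )
  if (n_programs > 2) {
    onsets <- seq(0.58, 0.84, length.out = n_programs - 2)
    for (k in seq_len(n_programs - 2)) {
      o <- onsets[k] + shift
      terminal <- k == n_programs - 2
      off <- if (terminal) Inf else onsets[k + 1] + shift - 0.06
      pats[[2 + k]] <- local({
        o_ <- o; off_ <- off
        function(t) {
          on <- 1 / (1 + exp(-(t - o_) / 0.08))
          if (is.finite(off_)) on * (1 / (1 + exp((t - off_) / 0.08))) else on
        }
      })
    }
  }
  pats[seq_len(n_programs)]
}

eval_patterns <- function(pats, t) {
  vapply(pats, function(f) f(t), numeric(length(t)))
}

#' Simulate a bifurcating expression trajectory with planted programs
#'
#' Generates a ground-truthed single-cell-like dataset: cells receive a
#' pseudotime uniform on \[0, 1\] and a branch label (`"root"` before the
#' bifurcation point, `"A"` or `"B"` after); temporal programs are smooth
#' non-negative curves (sigmoid onsets plus one transient bump) activated
#' sequentially along pseudotime, branch-specific after the bifurcation;
#' sparse non-negative gene loadings assign each gene to one (sometimes two)
#' programs; expression = loadings x patterns, degraded by multiplicative
#' lognormal noise and Bernoulli dropout to zero. The generator emulates the
#' smooth program structure of a differentiation trajectory, not the count
#' statistics of any real scRNA-seq dataset.
#'
#' @param n_cells,n_genes Dataset size (defaults 1000 cells, 2000 genes).
#' @param n_programs Number of planted programs (>= 2; default 4).
#' @param dropout_rate Bernoulli probability that an entry is zeroed
#'   (default 0.2).
#' @param noise_sd Standard deviation of the entry-wise multiplicative
#'   lognormal noise on the log scale (default 0.25; 0 gives exact
#'   `loadings x patterns`).
#' @param cell_noise_sd Standard deviation (log scale) of a per-cell
#'   multiplicative scale factor emulating residual library-size variation
#'   after normalization (default 0.35; 0 disables). This is the artifact a
#'   smoothness-constrained temporal factor is robust to and a free one
#'   absorbs cell-by-cell.
#' @param bifurcation Pseudotime of the branch point (default 0.5).
#' @param seed Integer seed.
#' @return A list with `data` (a [trajectory_dataset()]) and `truth` (class
#'   `ground_truth_programs`): `patterns` (per-branch function lists),
#'   `pattern_values` (cells x r matrix of true pattern values at each
#'   cell's pseudotime and lineage), `loadings` (r x genes), `membership`
#'   (list of member gene sets per program), `params`.
#' @export
simulate_bifurcating_expression <- function(n_cells = 1000, n_genes = 2000,
                                            n_programs = 4, dropout_rate = 0.2,
                                            noise_sd = 0.25, cell_noise_sd = 0.35,
                                            bifurcation = 0.5, seed = 1L) {
  if (n_programs < 2) abort("need n_programs >= 2.")
  if (n_cells < 1 || n_genes < 1) abort("n_cells and n_genes must be positive.")
  if (dropout_rate < 0 || dropout_rate > 1) abort("dropout_rate must be in [0, 1].")
  if (noise_sd < 0 || cell_noise_sd < 0) abort("noise sds must be >= 0.")
  set.seed(seed)

  t <- sort(runif(n_cells))
  ## balanced lineage allocation: half the cells follow each branch, in a
  ## random interleaving, so both lineages are evenly represented
  lineage <- sample(rep_len(c("A", "B"), n_cells))
  branch <- ifelse(t < bifurcation, "root", lineage)
  pats <- list(A = planted_patterns(n_programs, "A", bifurcation),
               B = planted_patterns(n_programs, "B", bifurcation))
  P <- matrix(0, n_cells, n_programs)
  for (b in c("A", "B")) {
    idx <- lineage == b
    P[idx, ] <- eval_patterns(pats[[b]], t[idx])
  }
  colnames(P) <- paste0("program", seq_len(n_programs))

  primary <- sample.int(n_programs, n_genes, replace = TRUE)
  L <- matrix(0, n_programs, n_genes)
  L[cbind(primary, seq_len(n_genes))] <- rgamma(n_genes, shape = 3, scale = 1) + 0.5
  secondary <- which(runif(n_genes) < 0.2)
  if (length(secondary) > 0) {
    sec_prog <- vapply(primary[secondary], function(p) {
      sample(setdiff(seq_len(n_programs), p), 1)
    }, integer(1))
    L[cbind(sec_prog, secondary)] <- (rgamma(length(secondary), 3, scale = 1) + 0.5) / 2
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  colnames(L) <- gene_ids
  rownames(L) <- colnames(P)

  E <- t(P %*% L)                                   # genes x cells
  if (noise_sd > 0) {
    E <- E * matrix(exp(rnorm(length(E), 0, noise_sd)), nrow(E), ncol(E))
  }
  if (cell_noise_sd > 0) {
    E <- sweep(E, 2, exp(rnorm(n_cells, 0, cell_noise_sd)), `*`)
  }
  if (dropout_rate > 0) {
    E[matrix(runif(length(E)) < dropout_rate, nrow(E), ncol(E))] <- 0
  }
  rownames(E) <- gene_ids
  colnames(E) <- cell_ids

  data <- trajectory_dataset(
    E, tibble(cell_id = cell_ids, pseudotime = t, branch = branch)
  )
  membership <- lapply(seq_len(n_programs), function(p) gene_ids[L[p, ] > 0])
  names(membership) <- colnames(P)
  truth <- structure(
    list(patterns = pats, pattern_values = P, loadings = L,
         membership = membership, lineage = lineage,
         params = list(n_cells = n_cells, n_genes = n_genes,
                       n_programs = n_programs, dropout_rate = dropout_rate,
                       noise_sd = noise_sd, cell_noise_sd = cell_noise_sd,
                       bifurcation = bifurcation,
                       seed = seed)),
    class = "ground_truth_programs"
  )
  list(data = data, truth = truth)
}

#' True pattern values restricted to a lineage subset
#'
#' Convenience for benchmarking: returns the planted pattern matrix for the
#' cells of a [subset_branch()] view, aligned to its cell order.
#'
#' @param truth `ground_truth_programs` from
#'   [simulate_bifurcating_expression()].
#' @param data The full simulated dataset's `trajectory_dataset`.
#' @param subset A `trajectory_dataset` whose cells are a subset of `data`'s.
#' @return Cells x r matrix of true pattern values.
#' @export
truth_patterns_for <- function(truth, data, subset) {
  idx <- match(subset$cells$cell_id, data$cells$cell_id)
  truth$pattern_values[idx, , drop = FALSE]
}
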