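# Non-negative least-squares refit of the temporal factor against fixed
# consensus gene coefficients, by exact HALS coordinate descent on A.
nnls_refit_A <- function(Y, X, n_sweeps = 10000, tol = 1e-13) {
  r <- nrow(X)
  A <- matrix(runif(nrow(Y) * r), nrow(Y), r)
  XXt <- tcrossprod(X)
  YXt <- Y %*% t(X)
  eps <- .Machine$double.eps
  scale <- max(abs(A))
  for (s in seq_len(n_sweeps)) {
    delta <- 0
    for (j in seq_len(r)) {
      d <- XXt[j, j]
      if (d > eps) {
        new <- pmax(0, A[, j] + (YXt[, j] - A %*% XXt[, j]) / d)
        delta <- max(delta, max(abs(new - A[, j])))
        A[, j] <- new
      }
    }
    scale <- max(scale, max(A))
    if (delta <= tol * max(scale, eps)) break
  }
  A
}

# Same refit under the spline constraint A = phi C^T: coordinate descent on
# the non-negative spline coefficients, so piNMF consensus patterns remain
# smooth non-negative functions of pseudotime.
nnls_refit_C <- function(Y, X, phi, n_sweeps = 20000, tol = 1e-13) {
  r <- nrow(X)
  K <- ncol(phi)
  C <- matrix(runif(r * K), r, K)
  ptp <- crossprod(phi)
  XXt <- tcrossprod(X)
  ptyxt <- crossprod(phi, Y %*% t(X))
  eps <- .Machine$double.eps
  for (s in seq_len(n_sweeps)) {
    delta <- 0
    for (j in seq_len(r)) {
      d <- XXt[j, j]
      if (d <= eps) next
      cj <- C[j, ]
      G <- ptp * d
      g <- ptyxt[, j] - ptp %*% (t(C) %*% XXt[, j]) + G %*% cj
      for (k in seq_len(K)) {
        cj[k] <- max(0, (g[k] - sum(G[k, ] * cj) + G[k, k] * cj[k]) / G[k, k])
      }
      delta <- max(delta, max(abs(cj - C[j, ])))
      C[j, ] <- cj
    }
    if (delta <= tol * max(max(C), eps)) break
  }
  phi %*% t(C)
}

l2_normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' Consensus gene expression programs across factorization replicates
#'
#' Pools the r components of every replicate as L2-normalized
#' gene-coefficient vectors (rows of X), clusters them by K-means with
#' Euclidean distance and k = rank, and takes cluster centroids as the
#' consensus gene-coefficient matrix. The temporal factor is then recovered
#' by a single non-negative least-squares refit against the consensus gene
#' coefficients. Stability is summarized by the mean silhouette width of the
#' clustered component vectors, and reconstruction error by the Frobenius
#' norm of the residual.
#'
#' @param data The [trajectory_dataset()] the replicates were fit on (needed
#'   for the temporal refit and the Frobenius error).
#' @param replicates List of `nmf_fit` objects with a shared rank and gene set.
#' @param rank Consensus rank (number of K-means clusters); defaults to the
#'   replicates' rank.
#' @param basis The [build_spline_basis()] the replicates were fit with
#'   (required for piNMF replicates, so the consensus temporal factor keeps
#'   the spline constraint; ignored for stdNMF).
#' @param kmeans_seed Seed for the K-means initialization (deterministic
#'   consensus).
#' @return Object of class `nmf_consensus`: `consensus_A` (cells x r, columns
#'   scaled to unit maximum), `consensus_X` (r x genes centroids),
#'   `replicate_cluster_labels`, `silhouette`, `frobenius_error`,
#'   `activations` (cells x r, min-max scaled to \[0, 1\]),
#'   `program_distance` (r x r Euclidean distances), `rank`, `mode`, `cells`.
#' @export
consensus_programs <- function(data, replicates, rank = NULL, basis = NULL,
                               kmeans_seed = 0L) {
  stopifnot(inherits(data, "trajectory_dataset"))
  if (length(replicates) < 2) abort("need >= 2 replicates for a consensus.")
  ranks <- vapply(replicates, function(f) f$rank, integer(1))
  if (length(unique(ranks)) != 1) abort("replicates have mismatched ranks.")
  gene_sets <- vapply(replicates, function(f) paste(f$gene_ids, collapse = "\r"),
                      character(1))
  if (length(unique(gene_sets)) != 1) abort("replicates have mismatched gene sets.")
  if (is.null(rank)) rank <- ranks[1]

  pool <- do.call(rbind, lapply(replicates, function(f) l2_normalize_rows(f$X)))
  km <- NULL
  for (try in 0:9) {
    set.seed(kmeans_seed + try)
    km <- tryCatch(
      kmeans(pool, centers = rank, nstart = 10, iter.max = 200),
      error = function(e) NULL
    )
    if (!is.null(km) && all(tabulate(km$cluster, rank) > 0)) break
    km <- NULL
  }
  if (is.null(km)) abort("K-means produced an empty cluster after 10 retries.")

  consensus_X <- km$centers
  rownames(consensus_X) <- paste0("program", seq_len(rank))
  colnames(consensus_X) <- replicates[[1]]$gene_ids

  sil <- if (nrow(pool) > rank) {
    mean(cluster::silhouette(km$cluster, dist(pool))[, "sil_width"])
  } else NA_real_

  mode <- replicates[[1]]$mode
  Y <- t(data$expr)
  set.seed(kmeans_seed)
  A <- if (identical(mode, "pinmf")) {
    if (is.null(basis)) {
      abort("piNMF replicates need `basis` for the constrained temporal refit.")
    }
    nnls_refit_C(Y, consensus_X, basis$basis)
  } else {
    nnls_refit_A(Y, consensus_X)
  }
  for (j in seq_len(rank)) {
    s <- max(A[, j])
    if (s > 0) {
      A[, j] <- A[, j] / s
      consensus_X[j, ] <- consensus_X[j, ] * s
    }
  }
  dimnames(A) <- list(colnames(data$expr), rownames(consensus_X))
  frob <- sqrt(sum((Y - A %*% consensus_X)^2))

  res <- structure(
    list(consensus_A = A, consensus_X = consensus_X,
         replicate_cluster_labels = km$cluster,
         silhouette = sil, frobenius_error = frob,
         activations = NULL,
         program_distance = NULL,
         rank = rank, mode = replicates[[1]]$mode,
         cells = data$cells),
    class = "nmf_consensus"
  )
  res$activations <- activation_scale(res)
  res$program_distance <- program_distance(res)
  res
}

#' @export
print.nmf_consensus <- function(x, ...) {
  cat(sprintf(
    "<nmf_consensus> %s rank %d; silhouette %.3f; Frobenius error %.4g\n",
    x$mode, x$rank, x$silhouette, x$frobenius_error
  ))
  invisible(x)
}

#' Min-max activation scaling of consensus temporal patterns
#'
#' Rescales each consensus program column across cells to \[0, 1\] ("0 to 1
#' denotes activation"). Constant columns cannot be scaled and are returned
#' as all zeros with a warning.
#'
#' @param consensus An `nmf_consensus` object (or a bare cells x r matrix).
#' @return Cells x r matrix of activations in \[0, 1\].
#' @export
activation_scale <- function(consensus) {
  A <- if (inherits(consensus, "nmf_consensus")) consensus$consensus_A else as.matrix(consensus)
  out <- A
  for (j in seq_len(ncol(A))) {
    rng <- range(A[, j])
    if (diff(rng) == 0) {
      warn(sprintf("program %d has constant activation; returning zeros.", j))
      out[, j] <- 0
    } else {
      out[, j] <- (A[, j] - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' Pairwise Euclidean distance between consensus programs
#'
#' Distances between L2-normalized consensus gene-coefficient vectors; large
#' values indicate well-separated programs and support the rank selection.
#'
#' @param consensus An `nmf_consensus` object (or a bare r x genes matrix).
#' @return Symmetric r x r matrix with zero diagonal.
#' @export
program_distance <- function(consensus) {
  X <- if (inherits(consensus, "nmf_consensus")) consensus$consensus_X else as.matrix(consensus)
  D <- as.matrix(dist(l2_normalize_rows(X)))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Stability/error diagnostics across candidate factorization ranks
#'
#' Runs a replicate ensemble and consensus at each candidate rank and
#' tabulates the mean silhouette width (stability) and Frobenius
#' reconstruction errors (consensus fit, and the best single replicate).
#' The rank maximizing stability while keeping the error low is the usual
#' choice.
#'
#' @inheritParams fit_replicate
#' @param ranks Integer vector of candidate ranks, each >= 2 (the silhouette
#'   is undefined for a single cluster).
#' @return A tibble with columns `rank`, `silhouette`, `frobenius_error`,
#'   `best_replicate_error`.
#' @export
rank_sweep <- function(data, basis = NULL, ranks, config) {
  if (any(ranks < 2)) abort("every candidate rank must be >= 2.")
  purrr::map_dfr(ranks, function(r) {
    cfg <- config
    cfg$rank <- as.integer(r)
    reps <- run_ensemble(data, basis, cfg)
    cons <- consensus_programs(data, reps, rank = r, basis = basis)
    best <- sqrt(min(vapply(
      reps, function(f) utils::tail(f$objective_trace, 1), numeric(1)
    )))
    tibble(rank = r, silhouette = cons$silhouette,
           frobenius_error = cons$frobenius_error,
           best_replicate_error = best)
  })
}
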