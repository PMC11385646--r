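#' Factorization configuration
#'
#' Bundles the solver and ensemble settings: factorization rank, mode
#' (`"pinmf"` constrains temporal patterns to non-negative spline functions
#' of pseudotime; `"stdnmf"` leaves the temporal factor free), stopping
#' criteria (maximum 1e4 sweeps, relative objective decrease below 1e-10),
#' ensemble size (750 random-restart replicates) and base seed.
#'
#' @param rank Factorization rank r (>= 1).
#' @param mode `"pinmf"` or `"stdnmf"`.
#' @param max_iter Maximum number of HALS sweeps.
#' @param tol Relative objective-decrease stopping tolerance.
#' @param n_replicates Ensemble size for [run_ensemble()].
#' @param base_seed Base seed; replicate i uses `base_seed + i`.
#' @return A list of class `factorization_config`.
#' @export
factorization_config <- function(rank, mode = c("pinmf", "stdnmf"),
                                 max_iter = 1e4, tol = 1e-10,
                                 n_replicates = 750, base_seed = 1L) {
  mode <- match.arg(mode)
  if (rank < 1) abort("rank must be >= 1.")
  if (tol <= 0) abort("tol must be > 0.")
  if (n_replicates < 1) abort("n_replicates must be >= 1.")
  structure(
    list(rank = as.integer(rank), mode = mode, max_iter = as.integer(max_iter),
         tol = tol, n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed)),
    class = "factorization_config"
  )
}

# One exact HALS block-coordinate sweep guarantees a non-increasing squared
# Frobenius objective ||Y - A X||_F^2; Y is cells x genes internally.
hals_core <- function(Y, rank, mode, phi = NULL, max_iter, tol, seed) {
  set.seed(seed)
  n <- nrow(Y)
  m <- ncol(Y)
  if (rank > min(n, m)) {
    abort(sprintf("rank %d exceeds min(cells, genes) = %d.", rank, min(n, m)))
  }
  pinmf <- identical(mode, "pinmf")
  if (pinmf) {
    if (is.null(phi)) abort("pinmf mode needs a spline basis.")
    if (nrow(phi) != n) abort("basis rows must align with cells.")
    K <- ncol(phi)
    ptp <- crossprod(phi)
  }
  normY2 <- sum(Y^2)
  if (normY2 == 0) {
    warn("all-zero expression matrix: returning zero factors.")
    C <- if (pinmf) matrix(0, rank, K) else NULL
    A <- matrix(0, n, rank)
    return(list(A = A, X = matrix(0, rank, m), C = C,
                objective_trace = 0, converged = TRUE, n_iter = 0L, seed = seed))
  }

  if (pinmf) {
    C <- matrix(runif(rank * K), rank, K)
    A <- phi %*% t(C)
  } else {
    C <- NULL
    A <- matrix(runif(n * rank), n, rank)
  }
  X <- matrix(runif(rank * m), rank, m)

  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  eps <- .Machine$double.eps

  while (it < max_iter) {
    it <- it + 1L
    ## X block, one exact HALS pass per row
    AtY <- crossprod(A, Y)
    AtA <- crossprod(A)
    for (j in seq_len(rank)) {
      d <- AtA[j, j]
      if (d > eps) {
        X[j, ] <- pmax(0, X[j, ] + (AtY[j, ] - AtA[j, ] %*% X) / d)
      }
    }
    XXt <- tcrossprod(X)
    if (pinmf) {
      ## spline-coefficient block: exact coordinate descent on each row of C,
      ## keeping A = phi C^T at all times
      ptyxt <- crossprod(phi, Y %*% t(X))          # K x r
      for (j in seq_len(rank)) {
        d <- XXt[j, j]
        if (d <= eps) next
        cj <- C[j, ]
        G <- ptp * d
        g <- ptyxt[, j] - ptp %*% (t(C) %*% XXt[, j]) + G %*% cj
        for (pass in 1:2) {
          for (k in seq_len(ncol(phi))) {
            ck <- (g[k] - sum(G[k, ] * cj) + G[k, k] * cj[k]) / G[k, k]
            cj[k] <- max(0, ck)
          }
        }
        C[j, ] <- cj
      }
      A <- phi %*% t(C)
    } else {
      YXt <- Y %*% t(X)
      for (j in seq_len(rank)) {
        d <- XXt[j, j]
        if (d > eps) {
          A[, j] <- pmax(0, A[, j] + (YXt[, j] - A %*% XXt[, j]) / d)
        }
      }
    }
    ## objective via trace identity, avoids forming A X
    AtA <- crossprod(A)
    AtY <- crossprod(A, Y)
    obj <- normY2 - 2 * sum(AtY * X) + sum(AtA * tcrossprod(X))
    obj <- max(obj, 0)
    if (obj > prev) {            # sub-rounding fluctuation: stop, keep trace monotone
      converged <- TRUE
      break
    }
    trace <- c(trace, obj)
    if (is.finite(prev) && (prev - obj) <= tol * max(prev, eps)) {
      converged <- TRUE
      prev <- obj
      break
    }
    prev <- obj
  }

  ## scale convention: each temporal pattern to unit maximum, X compensates,
  ## so A X is unchanged
  for (j in seq_len(rank)) {
    s <- max(A[, j])
    if (s > 0) {
      A[, j] <- A[, j] / s
      if (pinmf) C[j, ] <- C[j, ] / s
      X[j, ] <- X[j, ] * s
    }
  }
  list(A = A, X = X, C = C, objective_trace = trace,
       converged = converged, n_iter = it, seed = seed)
}

#' Fit one factorization replicate by hierarchical alternating least squares
#'
#' Minimizes the squared Frobenius distance between the expression matrix and
#' the reconstruction `A %*% X` under non-negativity, alternating exact
#' block-coordinate updates of the gene-coefficient matrix `X` and either the
#' temporal factor `A` (stdNMF) or the spline coefficients `C` with
#' `A = Phi %*% t(C)` (piNMF). The objective is non-increasing at every
#' sweep; iteration stops when the relative decrease falls below `tol` or
#' after `max_iter` sweeps. After convergence each temporal pattern column is
#' rescaled to unit maximum with a compensating rescale of `X`.
#'
#' @param data A [trajectory_dataset()].
#' @param basis A [build_spline_basis()] result (required for piNMF mode,
#'   ignored for stdNMF).
#' @param config A [factorization_config()].
#' @param seed Integer seed for the random uniform(0,1] initialization.
#' @return An object of class `nmf_fit`: `A` (cells x r temporal patterns,
#'   columns scaled to max 1), `X` (r x genes gene coefficients), `C` (r x K
#'   spline coefficients, piNMF only), `objective_trace` (non-increasing
#'   squared Frobenius residuals), `converged`, `n_iter`, `seed`, `rank`,
#'   `mode`, plus cell/gene identifiers.
#' @export
fit_replicate <- function(data, basis = NULL, config, seed) {
  stopifnot(inherits(data, "trajectory_dataset"),
            inherits(config, "factorization_config"))
  Y <- t(data$expr)                       # cells x genes
  phi <- if (config$mode == "pinmf") basis$basis else NULL
  fit <- hals_core(Y, config$rank, config$mode, phi,
                   config$max_iter, config$tol, as.integer(seed))
  fit$rank <- config$rank
  fit$mode <- config$mode
  fit$cell_ids <- colnames(data$expr)
  fit$gene_ids <- rownames(data$expr)
  dimnames(fit$A) <- list(fit$cell_ids, paste0("program", seq_len(config$rank)))
  dimnames(fit$X) <- list(paste0("program", seq_len(config$rank)), fit$gene_ids)
  class(fit) <- "nmf_fit"
  fit
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "<nmf_fit> %s rank %d; %d cells x %d genes; %d sweeps, %sconverged; objective %.6g\n",
    x$mode, x$rank, nrow(x$A), ncol(x$X), x$n_iter,
    if (x$converged) "" else "NOT ", utils::tail(x$objective_trace, 1)
  ))
  invisible(x)
}

#' Run a seeded ensemble of factorization replicates
#'
#' Fits `config$n_replicates` independent random-restart replicates; replicate
#' i is seeded with `base_seed + i`, so the ensemble is reproducible and
#' order-deterministic.
#'
#' @inheritParams fit_replicate
#' @return List of `nmf_fit` objects, one per replicate.
#' @export
run_ensemble <- function(data, basis = NULL, config) {
  stopifnot(inherits(config, "factorization_config"))
  if (config$n_replicates < 1) abort("n_replicates must be >= 1.")
  purrr::map(seq_len(config$n_replicates), function(i) {
    tryCatch(
      fit_replicate(data, basis, config, seed = config$base_seed + i),
      error = function(e) {
        abort(sprintf("replicate %d failed: %s", i, conditionMessage(e)))
      }
    )
  })
}
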