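#' Clamped B-spline basis over pseudotime
#'
#' Builds the non-negative temporal basis used by the pseudotime-informed
#' factorization: a clamped (boundary-knot-replicated) B-spline basis of the
#' given degree with `n_knots` interior breakpoints placed at pseudotime
#' quantiles, evaluated at every cell's pseudotime and row-normalized so each
#' row sums to one (partition of unity). Temporal patterns are then
#' non-negative combinations `A = Phi %*% t(C)` of these basis functions, so
#' non-negative spline coefficients suffice for non-negative patterns.
#'
#' @param pseudotime Numeric vector of per-cell pseudotimes (finite).
#' @param n_knots Number of interior knots (default 4).
#' @param degree Spline degree (default 3, cubic).
#' @return An object of class `spline_basis`: list with `basis` (cells x K
#'   matrix, K = n_knots + degree + 1), `knots`, `boundary`, `degree`,
#'   `pseudotime`.
#' @export
build_spline_basis <- function(pseudotime, n_knots = 4, degree = 3) {
  if (anyNA(pseudotime) || any(!is.finite(pseudotime))) {
    abort("pseudotime contains NA or non-finite values.")
  }
  if (n_knots < 1 || degree < 1) abort("need n_knots >= 1 and degree >= 1.")
  K <- n_knots + degree + 1
  n_distinct <- length(unique(pseudotime))
  if (n_distinct < K) {
    abort(sprintf(
      "degenerate input: %d distinct pseudotime values < basis dimension K = %d.",
      n_distinct, K
    ))
  }
  boundary <- range(pseudotime)
  probs <- seq_len(n_knots) / (n_knots + 1)
  interior <- as.numeric(quantile(unique(pseudotime), probs = probs, names = FALSE))
  # clamp: replicate boundary knots degree+1 times
  knots_full <- c(rep(boundary[1], degree + 1), interior, rep(boundary[2], degree + 1))
  phi <- splines::splineDesign(knots_full, pseudotime, ord = degree + 1,
                               outer.ok = FALSE)
  # clamped B-splines already form a partition of unity; normalize to absorb
  # floating-point residue and make the row-sum invariant exact by construction
  phi <- phi / rowSums(phi)
  structure(
    list(basis = phi, knots = interior, boundary = boundary,
         degree = degree, n_knots = n_knots, pseudotime = pseudotime),
    class = "spline_basis"
  )
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf(
    "<spline_basis> degree %d, %d interior knots, K = %d basis functions, %d cells\n",
    x$degree, x$n_knots, ncol(x$basis), nrow(x$basis)
  ))
  invisible(x)
}
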