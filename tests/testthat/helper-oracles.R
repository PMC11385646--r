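# Independent reference implementations used only to audit the package's
# algorithms. Each is written against the mathematical definition, not the
# package's code paths.

# Multiplicative-update NMF (Lee-Seung, squared Frobenius objective), run
# from the same random initialization the HALS solver uses for stdNMF.
mu_nmf_oracle <- function(Y, rank, seed, max_iter = 20000, tol = 1e-14) {
  set.seed(seed)
  n <- nrow(Y); m <- ncol(Y)
  A <- matrix(runif(n * rank), n, rank)
  X <- matrix(runif(rank * m), rank, m)
  eps <- 1e-12
  prev <- Inf
  for (it in seq_len(max_iter)) {
    A <- A * (Y %*% t(X)) / (A %*% X %*% t(X) + eps)
    X <- X * (t(A) %*% Y) / (t(A) %*% (A %*% X) + eps)
    obj <- sum((Y - A %*% X)^2)
    if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, eps)) break
    prev <- obj
  }
  list(objective = sum((Y - A %*% X)^2), A = A, X = X)
}

# Mean silhouette width from first principles (pairwise Euclidean distances).
silhouette_oracle <- function(points, labels) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Exhaustive PWM score-tail oracle: enumerate all 4^L sequences.
pwm_tail_oracle <- function(pwm, scaled_score, background = rep(0.25, 4)) {
  m <- pwm$matrix
  L <- nrow(m)
  combos <- as.matrix(expand.grid(rep(list(1:4), L)))
  raw <- rowSums(matrix(m[cbind(rep(seq_len(L), each = nrow(combos)),
                                as.vector(combos))],
                        nrow(combos), L))
  lo <- sum(apply(m, 1, min)); hi <- sum(apply(m, 1, max))
  scaled <- (raw - lo) / (hi - lo)
  w <- apply(combos, 1, function(idx) prod(background[idx]))
  sum(w[scaled >= scaled_score])
}

# Small hand-specified PWM from a count matrix (rows = positions, A C G T).
toy_pwm <- function(counts, id = "toy", tf = "TOY", pseudocount = 0.8) {
  counts <- as.matrix(counts)
  colnames(counts) <- c("A", "C", "G", "T")
  prob <- (counts + pseudocount / 4) / (rowSums(counts) + pseudocount)
  structure(list(id = id, tf = tf, matrix = prob), class = "pwm_record")
}

# Precision/recall/F1 of estimated module memberships against planted truth,
# pairing programs by the supplied matching.
module_f1_oracle <- function(assignment, truth, matching) {
  mem <- module_members(assignment)
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(matching))) {
    est <- mem[[matching$program_a[i]]]
    if (is.null(est)) est <- character(0)
    tru <- truth$membership[[matching$program_b[i]]]
    tp <- tp + length(intersect(est, tru))
    fp <- fp + length(setdiff(est, tru))
    fn <- fn + length(setdiff(tru, est))
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = tp / (tp + fn),
       f1 = 2 * tp / (2 * tp + fp + fn))
}

# Benchmark-scale simulated lineage shared by the heavier tests: one
# bifurcating dataset restricted to the root + A branch, with its basis and
# planted patterns.
benchmark_lineage <- function(seed, n_cells = 300, n_genes = 400, ...) {
  sim <- simulate_bifurcating_expression(n_cells = n_cells, n_genes = n_genes,
                                         seed = seed, ...)
  dA <- subset_branch(sim$data, "A")
  list(
    sim = sim,
    data = dA,
    basis = build_spline_basis(dA$cells$pseudotime),
    truth_patterns = truth_patterns_for(sim$truth, sim$data, dA)
  )
}
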