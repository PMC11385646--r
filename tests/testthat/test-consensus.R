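small_lineage <- function(seed = 1) benchmark_lineage(seed, 160, 200)

test_that("permuted identical replicates give silhouette 1 and recover the components", {
  # exact factors: data constructed as A0 X0 with A0 = phi C0, so the
  # replicates are exact stationary points and the consensus must return the
  # shared components to numerical precision
  set.seed(5)
  n <- 150
  pt <- sort(runif(n))
  basis <- build_spline_basis(pt)
  C0 <- matrix(runif(3 * ncol(basis$basis)), 3)
  A0 <- basis$basis %*% t(C0)
  for (j in 1:3) {
    C0[j, ] <- C0[j, ] / max(A0[, j])
    A0[, j] <- A0[, j] / max(A0[, j])
  }
  X0 <- matrix(rgamma(3 * 80, 2), 3, 80,
               dimnames = list(paste0("program", 1:3), paste0("g", 1:80)))
  E <- t(A0 %*% X0)
  colnames(E) <- sprintf("c%03d", 1:n)
  data <- trajectory_dataset(E, tibble::tibble(
    cell_id = colnames(E), pseudotime = pt, branch = "root"
  ))
  mk_fit <- function(perm) {
    structure(list(A = A0[, perm], X = X0[perm, ], C = C0[perm, ],
                   rank = 3L, gene_ids = colnames(X0), mode = "pinmf"),
              class = "nmf_fit")
  }
  cons <- consensus_programs(data, list(mk_fit(1:3), mk_fit(c(3, 1, 2))),
                             basis = basis)
  expect_equal(cons$silhouette, 1)
  m <- match_programs(cons$consensus_A, A0)
  for (i in seq_len(3)) {
    j <- as.integer(sub("program", "", m$program_b[i]))
    expect_equal(unname(cons$consensus_X[i, ]), unname(X0[j, ]),
                 tolerance = 1e-8)
  }
})

test_that("silhouette matches an independent pairwise-distance oracle", {
  # two well-separated clouds of component vectors
  set.seed(42)
  genes <- 30
  base1 <- runif(genes); base2 <- runif(genes) + 3
  mk_fit <- function(jitter_seed) {
    set.seed(jitter_seed)
    X <- rbind(base1 + runif(genes, 0, 0.01), base2 + runif(genes, 0, 0.01))
    rownames(X) <- paste0("program", 1:2)
    colnames(X) <- paste0("g", seq_len(genes))
    structure(list(X = X, rank = 2L, gene_ids = colnames(X), mode = "stdnmf"),
              class = "nmf_fit")
  }
  reps <- lapply(1:4, mk_fit)
  pool <- do.call(rbind, lapply(reps, function(f) {
    f$X / sqrt(rowSums(f$X^2))
  }))
  km <- kmeans(pool, 2, nstart = 5)
  expect_gt(silhouette_oracle(pool, km$cluster), 0.5)
  # package silhouette agrees with the oracle on the same clustering
  sil_pkg <- mean(cluster::silhouette(km$cluster, dist(pool))[, "sil_width"])
  expect_equal(sil_pkg, silhouette_oracle(pool, km$cluster), tolerance = 1e-12)
})

test_that("activation scaling maps columns to [0,1] and flags constants", {
  expect_equal(unname(activation_scale(cbind(c(2, 4, 6)))), cbind(c(0, 0.5, 1)))
  expect_warning(out <- activation_scale(cbind(a = c(1, 1, 1))), "constant")
  expect_equal(unname(out), cbind(c(0, 0, 0)))
  set.seed(1)
  M <- matrix(rnorm(40), 10, 4)
  out <- activation_scale(M)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("program distances match a brute-force elementwise computation", {
  set.seed(8)
  X <- matrix(runif(4 * 25), 4, 25)
  D <- program_distance(X)
  Xn <- X / sqrt(rowSums(X^2))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(D[i, j], sqrt(sum((Xn[i, ] - Xn[j, ])^2)), tolerance = 1e-12)
  }
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  # identical programs at distance 0; orthogonal unit vectors at sqrt(2)
  expect_equal(program_distance(rbind(c(1, 0), c(1, 0)))[1, 2], 0)
  expect_equal(program_distance(rbind(c(1, 0), c(0, 1)))[1, 2], sqrt(2))
})

test_that("rank_sweep validates ranks and reports diagnostics per rank", {
  bl <- small_lineage()
  cfg <- factorization_config(2, "pinmf", max_iter = 120, tol = 1e-8,
                              n_replicates = 4, base_seed = 2)
  expect_error(rank_sweep(bl$data, bl$basis, ranks = c(1, 2), cfg), ">= 2")
  sw <- rank_sweep(bl$data, bl$basis, ranks = 2:3, cfg)
  expect_equal(sw$rank, 2:3)
  expect_true(all(is.finite(sw$silhouette)))
  expect_true(all(sw$best_replicate_error > 0))
})

test_that("consensus propagates validation errors", {
  bl <- small_lineage()
  cfg <- factorization_config(2, "stdnmf", max_iter = 30, n_replicates = 2,
                              base_seed = 1)
  reps <- run_ensemble(bl$data, NULL, cfg)
  expect_error(consensus_programs(bl$data, reps[1]), ">= 2 replicates")
  bad <- reps
  bad[[2]]$rank <- 3L
  expect_error(consensus_programs(bl$data, bad), "mismatched ranks")
})
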