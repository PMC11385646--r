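#' Assign genes to (semi)discrete modules by multiple least squares regression
#'
#' Each gene's expression is z-scored across cells and regressed (ordinary
#' least squares, no intercept: the response is centered) on the r consensus
#' activation columns. A
#' two-sided t-test per coefficient, Benjamini-Hochberg corrected jointly
#' across all gene x program tests, determines membership: a gene belongs to
#' every program with q < alpha and a positive coefficient, so a gene may sit
#' in more than one module.
#'
#' @param data A [trajectory_dataset()] (same cells as the consensus).
#' @param consensus An `nmf_consensus` object.
#' @param alpha FDR threshold for membership (default 0.05).
#' @return A tibble of class `gene_module_assignment` with one row per
#'   gene x program: `gene`, `program`, `estimate`, `p.value`, `q.value`,
#'   `member`. Zero-variance genes are excluded (message with count).
#' @export
assign_gene_modules <- function(data, consensus, alpha = 0.05) {
  stopifnot(inherits(data, "trajectory_dataset"),
            inherits(consensus, "nmf_consensus"))
  act <- consensus$activations
  if (nrow(act) != ncol(data$expr)) {
    abort("consensus activations do not align with the dataset's cells.")
  }
  E <- data$expr
  sds <- apply(E, 1, sd)
  drop_n <- sum(sds == 0)
  if (drop_n > 0) {
    inform(sprintf("excluding %d zero-variance gene(s) from module assignment.",
                   drop_n))
  }
  keep <- sds > 0
  Z <- t((E[keep, , drop = FALSE] - rowMeans(E[keep, , drop = FALSE])) / sds[keep])

  # the response is z-scored (centered), so the regression is on the r
  # activation columns alone; an intercept would be near-collinear with
  # programs that tile pseudotime (their activations sum to ~1)
  D <- act
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    abort("activation columns are collinear: rank-deficient design.")
  }
  DtD_inv <- chol2inv(chol(crossprod(D)))
  B <- DtD_inv %*% crossprod(D, Z)                # r x genes
  res <- Z - D %*% B
  df <- nrow(D) - ncol(D)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(DtD_inv), sigma2))        # r x genes
  tstat <- B / se
  pval <- 2 * pt(-abs(tstat), df = df)

  genes <- colnames(Z)
  out <- tidyr::expand_grid(gene = genes, program = colnames(act))
  out$estimate <- as.vector(B)
  out$p.value <- as.vector(pval)
  out$q.value <- p.adjust(out$p.value, method = "BH")
  out$member <- out$q.value < alpha & out$estimate > 0
  attr(out, "alpha") <- alpha
  class(out) <- c("gene_module_assignment", class(out))
  out
}

#' Extract member gene sets per program
#'
#' @param assignment A [assign_gene_modules()] result.
#' @return Named list of character vectors of member genes per program.
#' @export
module_members <- function(assignment) {
  split(assignment$gene[assignment$member], assignment$program[assignment$member])
}

#' Match programs between two consensus results by pattern correlation
#'
#' Greedy exhaustive matching (over all permutations for r <= 7) of program
#' columns maximizing the summed Pearson correlation between activation
#' patterns, used to pair piNMF and stdNMF modules before computing overlap.
#'
#' @param consA,consB `nmf_consensus` objects (or cells x r activation
#'   matrices) over the same cells.
#' @return A tibble `program_a`, `program_b`, `correlation`.
#' @export
match_programs <- function(consA, consB) {
  A <- if (inherits(consA, "nmf_consensus")) consA$activations else as.matrix(consA)
  B <- if (inherits(consB, "nmf_consensus")) consB$activations else as.matrix(consB)
  r <- ncol(A)
  if (ncol(B) != r) abort("both results must have the same rank.")
  cors <- suppressWarnings(cor(A, B))
  cors[is.na(cors)] <- 0
  if (r <= 7) {
    perms <- perms_of(r)
    scores <- vapply(perms, function(p) sum(cors[cbind(seq_len(r), p)]), numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    # greedy fallback for large ranks
    best <- integer(r)
    avail <- seq_len(r)
    for (i in order(-apply(cors, 1, max))) {
      j <- avail[which.max(cors[i, avail])]
      best[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  tibble(
    program_a = colnames(A) %||% paste0("program", seq_len(r)),
    program_b = (colnames(B) %||% paste0("program", seq_len(r)))[best],
    correlation = cors[cbind(seq_len(r), best)]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

perms_of <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(perms_of(n - 1L), function(p) c(i, setdiff(seq_len(n), i)[p]))
  }))
}

#' Module-membership overlap between two assignments
#'
#' For each matched module pair, the percentage of the reference module's
#' genes recovered in the other module: `100 * |A intersect B| / |A|`
#' (asymmetric reference-set convention). Programs are paired via `matching`
#' (e.g. from [match_programs()]); by default programs with identical names
#' are paired.
#'
#' @param assignA Reference [assign_gene_modules()] result.
#' @param assignB Comparison assignment over the same gene universe.
#' @param matching Optional tibble with columns `program_a`, `program_b`.
#' @return Tibble `program_a`, `program_b`, `n_ref`, `n_other`,
#'   `n_shared`, `overlap_pct`.
#' @export
module_overlap <- function(assignA, assignB, matching = NULL) {
  memA <- module_members(assignA)
  memB <- module_members(assignB)
  progsA <- sort(unique(assignA$program))
  if (is.null(matching)) {
    matching <- tibble(program_a = progsA, program_b = progsA)
  }
  purrr::pmap_dfr(matching[, c("program_a", "program_b")], function(program_a, program_b) {
    a <- memA[[program_a]] %||% character(0)
    b <- memB[[program_b]] %||% character(0)
    if (length(a) == 0) {
      warn(sprintf("reference module %s is empty; overlap 0.", program_a))
    }
    tibble(
      program_a = program_a, program_b = program_b,
      n_ref = length(a), n_other = length(b),
      n_shared = length(intersect(a, b)),
      overlap_pct = if (length(a) == 0) 0 else 100 * length(intersect(a, b)) / length(a)
    )
  })
}
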