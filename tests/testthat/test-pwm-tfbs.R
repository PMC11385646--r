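jaspar_text <- c(
  ">M001 TFA",
  "A [ 10 0 0 2 ]",
  "C [ 0 10 0 2 ]",
  "G [ 0 0 10 2 ]",
  "T [ 0 0 0 4 ]",
  ">M002 TFB",
  "A [ 1 0 ]",
  "C [ 0 1 ]",
  "G [ 0 0 ]",
  "T [ 0 0 ]"
)

test_that("PWM parsing applies the pseudocount and normalizes positions", {
  pwms <- parse_pwms(jaspar_text)
  expect_length(pwms, 2)
  m <- pwms[[1]]$matrix
  expect_equal(dim(m), c(4, 4))
  expect_equal(rowSums(m), rep(1, 4), tolerance = 1e-9)
  expect_true(all(m > 0))
  # hand-computed: (10 + 0.2) / (10 + 0.8) and 0.2 / 10.8 for position 1
  expect_equal(unname(m[1, "A"]), 10.2 / 10.8, tolerance = 1e-12)
  expect_equal(unname(m[1, "C"]), 0.2 / 10.8, tolerance = 1e-12)
  # frequency rows (summing to 1) are accepted and re-normalized
  freq <- parse_pwms(c(">F X", "A [ 0.7 0.1 ]", "C [ 0.1 0.3 ]",
                       "G [ 0.1 0.3 ]", "T [ 0.1 0.3 ]"))
  expect_equal(rowSums(freq[[1]]$matrix), rep(1, 2), tolerance = 1e-9)
  expect_warning(expect_length(parse_pwms(""), 0), "empty")
  expect_error(parse_pwms(c(">bad B", "A [ 1 2 ]", "C [ 1 ]",
                            "G [ 1 2 ]", "T [ 1 2 ]")), "bad")
})

test_that("consensus scores 1, anti-consensus 0, arbitrary k-mers match brute force", {
  pwm <- toy_pwm(rbind(c(8, 1, 1, 0), c(0, 9, 1, 0),
                       c(2, 2, 2, 4), c(0, 0, 0, 10)))
  consensus <- paste(c("A", "C", "T", "T"), collapse = "")
  anti <- paste(c("T", "A", "A", "A")[c(1, 2, 3, 3)], collapse = "")
  # argmin base at each position
  anti <- paste(colnames(pwm$matrix)[apply(pwm$matrix, 1, which.min)],
                collapse = "")
  expect_equal(score_sequence(pwm, consensus), 1)
  expect_equal(score_sequence(pwm, anti), 0)
  set.seed(2)
  for (i in 1:10) {
    kmer <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                  collapse = "")
    m <- pwm$matrix
    raw <- sum(m[cbind(1:4, match(strsplit(kmer, "")[[1]],
                                  c("A", "C", "G", "T")))])
    lo <- sum(apply(m, 1, min)); hi <- sum(apply(m, 1, max))
    expect_equal(score_sequence(pwm, kmer), (raw - lo) / (hi - lo),
                 tolerance = 1e-12)
  }
  expect_error(score_sequence(pwm, "ACNT"), "ambiguous")
})

test_that("reverse-complement scoring is strand symmetric", {
  set.seed(3)
  counts <- matrix(rpois(6 * 4, 5), 6, 4)
  pwm <- toy_pwm(counts)
  for (i in 1:10) {
    kmer <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                  collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", kmer), "")[[1]]),
                collapse = "")
    expect_equal(score_sequence(pwm, kmer),
                 score_sequence(paleoprog:::revcomp_pwm(pwm), rc),
                 tolerance = 1e-12)
  }
})

test_that("match p-values equal exhaustive enumeration within one grid bin", {
  set.seed(4)
  for (L in c(3, 5, 8)) {
    pwm <- toy_pwm(matrix(rpois(L * 4, 4), L, 4))
    for (s in c(0, 0.31, 0.62, 0.9, 1)) {
      p_dp <- match_pvalue(pwm, s)
      # bracket the DP's one-bin discretization slack
      lo <- pwm_tail_oracle(pwm, s + 1e-4)
      hi <- pwm_tail_oracle(pwm, s - 1e-4)
      expect_gte(p_dp, lo - 1e-12)
      expect_lte(p_dp, hi + 1e-12)
    }
  }
  pwm <- toy_pwm(matrix(rpois(4 * 4, 4), 4, 4))
  expect_equal(match_pvalue(pwm, 0), 1)
  expect_equal(match_pvalue(pwm, 1.001), 0)
})

test_that("a planted motif-breaking variant is detected with positive delta", {
  # motif with consensus G at position 3; ref C destroys it, alt G restores it
  counts <- rbind(c(9, 0, 0, 0), c(0, 9, 0, 0), c(0, 0, 9, 0),
                  c(0, 0, 0, 9), c(9, 0, 0, 0), c(0, 0, 9, 0))
  pwm <- toy_pwm(counts, id = "M1", tf = "TF1")
  # context: consensus sequence ACGTAG with the variant at offset 3
  variants <- tibble::tibble(chrom = "chr1", pos = 100L, anc = "C", der = "G",
                             freq = 0.95, archaic_state = "ancestral")
  ctx <- list(`chr1:100` = list(
    seq = paste0("TTTTT", "AC", "C", "TAG", "TTTTT"), var_offset = 8L
  ))
  effects <- evaluate_variant(variants, ctx, list(pwm), p_threshold = 1e-3)
  expect_equal(nrow(effects), 1)
  expect_equal(effects$alt_score, 1)
  expect_gt(effects$delta, 0)
  # swapping ref and alt negates delta exactly (antisymmetry)
  v2 <- dplyr::mutate(variants, anc = "G", der = "C")
  ctx2 <- list(`chr1:100` = list(
    seq = paste0("TTTTT", "AC", "G", "TAG", "TTTTT"), var_offset = 8L
  ))
  e2 <- evaluate_variant(v2, ctx2, list(pwm), p_threshold = 1e-3)
  expect_equal(e2$delta, -effects$delta, tolerance = 1e-12)
})

test_that("a uniform PWM never passes the match threshold", {
  pwm <- toy_pwm(matrix(1, 5, 4))
  variants <- tibble::tibble(chrom = "chr1", pos = 50L, anc = "A", der = "T",
                             freq = 0.95, archaic_state = "ancestral")
  ctx <- list(`chr1:50` = list(seq = strrep("A", 21), var_offset = 11L))
  effects <- evaluate_variant(variants, ctx, list(pwm), p_threshold = 1e-4)
  expect_equal(nrow(effects), 0)
})

test_that("TF classification applies the fourth-quartile rule", {
  effects <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:8),
    motif = "m", tf = c(rep("TFA", 4), rep("TFB", 2), rep("TFC", 2)),
    strand = "+", offset = 0L,
    ref_score = 0.5, alt_score = 0.5,
    delta = c(0.99, 0.1, 0.05, 0.02, 0.97, -0.97, 0.01, -0.02),
    p.value = 1e-5, q.value = 1e-4
  )
  cls <- classify_tf_effects(effects)
  # |delta| 75th percentile over the 8 effects
  thr <- quantile(abs(effects$delta), 0.75, names = FALSE)
  expect_equal(sum(abs(effects$delta) >= thr),
               sum(cls$n_strong))
  a <- cls[cls$tf == "TFA", ]
  expect_equal(a$class, "increased")
  expect_equal(a$frequency_score, a$n_strong / 4)
  b <- cls[cls$tf == "TFB", ]
  expect_equal(b$class, "both")
  c_ <- cls[cls$tf == "TFC", ]
  expect_equal(c_$class, "none")
  expect_equal(c_$frequency_score, 0)
  # single strong positive effect -> increased with score 1
  one <- classify_tf_effects(effects[1, ])
  expect_equal(one$class, "increased")
  expect_equal(one$frequency_score, 1)
})
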