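test_that("peak atlas retains peaks by the 50% support-coverage rule", {
  reference <- tibble::tibble(chrom = "chr1",
                              start = c(1000L, 5000L, 9000L),
                              end = c(2000L, 6000L, 10000L))
  supports <- list(
    s1 = tibble::tibble(chrom = "chr1", start = c(1400L, 5600L),
                        end = c(2600L, 6600L))
  )
  atlas <- build_peak_atlas(reference, supports)
  # peak 1: 600/1000 covered -> kept; peak 2: 400/1000 -> dropped; peak 3: 0
  expect_equal(nrow(atlas), 1)
  expect_equal(atlas$start, 1000L)
  expect_equal(atlas$supported_by, "s1")
  # chrX peak arrives only via a sex-chromosome source, flagged
  atlas2 <- build_peak_atlas(reference, supports, sex_chrom_sources = list(
    x = tibble::tibble(chrom = "chrX", start = 100L, end = 700L)
  ))
  xrow <- atlas2[atlas2$chrom == "chrX", ]
  expect_equal(nrow(xrow), 1)
  expect_true(xrow$sex_chrom_added)
  expect_error(build_peak_atlas(reference, supports, min_frac = 0), "min_frac")
})

test_that("the island caller honors every clause of the definition", {
  sizes <- c(chr1 = 50000L)
  atlas <- tibble::tibble(chrom = "chr1", start = 9500L, end = 10500L)
  base_var <- tibble::tibble(chrom = "chr1", pos = 9999L, anc = "A", der = "G",
                             freq = 0.95, archaic_state = "ancestral")
  no_arch <- tibble::tibble(chrom = character(0), pos = integer(0))

  isl <- call_regulatory_islands(base_var, no_arch, atlas, chrom_sizes = sizes)
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start, isl$end), c(8499L, 11499L))
  expect_equal(isl$variants[[1]], 9999L)

  # below the (inclusive) frequency threshold
  v <- base_var; v$freq <- 0.85
  expect_equal(nrow(call_regulatory_islands(v, no_arch, atlas,
                                            chrom_sizes = sizes)), 0)
  v$freq <- 0.9   # threshold is inclusive
  expect_equal(nrow(call_regulatory_islands(v, no_arch, atlas,
                                            chrom_sizes = sizes)), 1)

  # archaic-derived contamination inside the window
  arch <- tibble::tibble(chrom = "chr1", pos = 10800L)
  expect_equal(nrow(call_regulatory_islands(base_var, arch, atlas,
                                            chrom_sizes = sizes)), 0)
  # contamination just outside the half-open window is tolerated
  arch_out <- tibble::tibble(chrom = "chr1", pos = 11499L)
  expect_equal(nrow(call_regulatory_islands(base_var, arch_out, atlas,
                                            chrom_sizes = sizes)), 1)

  # archaic state derived or missing disqualifies
  for (st in c("derived", "missing")) {
    v <- base_var; v$archaic_state <- st
    expect_equal(nrow(suppressMessages(call_regulatory_islands(
      v, no_arch, atlas, chrom_sizes = sizes
    ))), 0)
  }

  # window truncated by the chromosome end is rejected
  edge_atlas <- tibble::tibble(chrom = "chr1", start = 0L, end = 2000L)
  v <- base_var; v$pos <- 1000L
  expect_equal(nrow(call_regulatory_islands(v, no_arch, edge_atlas,
                                            chrom_sizes = sizes)), 0)

  # overlapping windows merge, pooling member variants
  v2 <- dplyr::bind_rows(base_var, dplyr::mutate(base_var, pos = 10400L))
  isl2 <- call_regulatory_islands(v2, no_arch, atlas, chrom_sizes = sizes)
  expect_equal(nrow(isl2), 1)
  expect_equal(isl2$width, 3401L)
  expect_equal(isl2$variants[[1]], c(9999L, 10400L))

  # variant outside any atlas peak does not qualify
  v <- base_var; v$pos <- 20000L
  expect_equal(nrow(call_regulatory_islands(v, no_arch, atlas,
                                            chrom_sizes = sizes)), 0)
})

test_that("the caller reproduces the simulator's brute-force truth sets", {
  n_match <- 0
  n_runs <- 60
  for (s in seq_len(n_runs)) {
    land <- suppressWarnings(simulate_regulatory_landscape(
      chrom_sizes = c(chr1 = 60000L, chr2 = 40000L),
      n_peaks = 15, n_variants = 40, seed = s
    ))
    got <- suppressMessages(call_regulatory_islands(
      land$variants, land$archaic_derived, land$peaks,
      chrom_sizes = land$chrom_sizes
    ))
    truth <- land$truth_islands
    same <- nrow(got) == nrow(truth) &&
      (nrow(got) == 0 ||
         (all(got$chrom == truth$chrom) && all(got$start == truth$start) &&
            all(got$end == truth$end) &&
            all(mapply(identical, got$variants,
                       lapply(truth$variants, function(v) sort(unname(v)))))))
    n_match <- n_match + same
  }
  expect_equal(n_match, n_runs)
})

test_that("landscape simulator edge cases behave as defined", {
  # no high-frequency variants -> empty truth set
  land <- suppressWarnings(simulate_regulatory_landscape(
    frac_high_freq = 0, seed = 2
  ))
  expect_equal(nrow(land$truth_islands), 0)
  # determinism
  l1 <- simulate_regulatory_landscape(seed = 5)
  l2 <- simulate_regulatory_landscape(seed = 5)
  expect_identical(l1$variants, l2$variants)
  expect_identical(l1$truth_islands, l2$truth_islands)
  # all-qualifying configuration: every merged window is an island
  land3 <- simulate_regulatory_landscape(
    frac_high_freq = 1, frac_archaic_ancestral = 1,
    archaic_derived_density = 0, seed = 3
  )
  expect_gt(nrow(land3$truth_islands), 0)
  got <- call_regulatory_islands(land3$variants, land3$archaic_derived,
                                 land3$peaks, chrom_sizes = land3$chrom_sizes)
  expect_equal(got$start, land3$truth_islands$start)
})

test_that("island-gene links follow GREAT-style regulatory domains", {
  sizes <- c(chr1 = 3000000L)
  tss <- tibble::tibble(
    gene = c("gA", "gB"),
    chrom = "chr1",
    position = c(1000000L, 1050000L),
    strand = c("+", "+")
  )
  dom <- regulatory_domains(tss, chrom_sizes = sizes)
  # basal: [995000, 1001000) and [1045000, 1051000); extensions meet between
  expect_equal(dom$start[dom$gene == "gA"], 0L)
  expect_equal(dom$end[dom$gene == "gA"], 1045000L)
  expect_equal(dom$start[dom$gene == "gB"], 1001000L)
  expect_equal(dom$end[dom$gene == "gB"], 2051000L)

  # island inside one basal domain -> one association
  isl <- tibble::tibble(chrom = "chr1", start = 996000L, end = 999000L)
  links <- link_islands_to_genes(isl, tss, chrom_sizes = sizes)
  expect_equal(links$gene, "gA")
  # island spanning the domain boundary -> both genes
  isl2 <- tibble::tibble(chrom = "chr1", start = 1044000L, end = 1046000L)
  links2 <- link_islands_to_genes(isl2, tss, chrom_sizes = sizes)
  expect_setequal(links2$gene, c("gA", "gB"))
  # island in a gene desert -> no associations
  isl3 <- tibble::tibble(chrom = "chr1", start = 2500000L, end = 2503000L)
  expect_equal(nrow(link_islands_to_genes(isl3, tss, chrom_sizes = sizes)), 0)
  # unknown strand treated as '+'
  tss2 <- dplyr::mutate(tss, strand = c("?", "+"))
  expect_message(regulatory_domains(tss2, chrom_sizes = sizes), "strand")
})

test_that("domain construction matches a brute-force oracle on a toy annotation", {
  set.seed(12)
  sizes <- c(chr1 = 2000000L)
  tss <- tibble::tibble(
    gene = paste0("g", 1:8),
    chrom = "chr1",
    position = sort(as.integer(runif(8, 10000, 1990000))),
    strand = sample(c("+", "-"), 8, replace = TRUE)
  )
  dom <- regulatory_domains(tss, chrom_sizes = sizes)
  # oracle: direct per-gene scan
  bas_start <- ifelse(tss$strand == "+", tss$position - 5000, tss$position - 1000)
  bas_end <- ifelse(tss$strand == "+", tss$position + 1000, tss$position + 5000)
  for (i in seq_len(8)) {
    others_before <- bas_end[-i][bas_end[-i] <= bas_start[i]]
    lo <- max(bas_start[i] - 1000000, 0,
              min(bas_start[i], if (length(others_before)) max(others_before) else -Inf))
    others_after <- bas_start[-i][bas_start[-i] >= bas_end[i]]
    hi <- min(bas_end[i] + 1000000, unname(sizes),
              max(bas_end[i], if (length(others_after)) min(others_after) else Inf))
    d <- dom[dom$gene == tss$gene[i], ]
    expect_equal(d$start, as.integer(lo))
    expect_equal(d$end, as.integer(hi))
  }
})

test_that("module island fractions are simple per-module proportions", {
  asg <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    program = c("p1", "p1", "p1", "p1", "p2"),
    estimate = 1, p.value = 0, q.value = 0,
    member = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  links <- tibble::tibble(island_id = "i1", chrom = "chr1", start = 0L,
                          end = 3000L, gene = c("g1", "g2", "g3"))
  fr <- suppressWarnings(module_island_fraction(asg, links))
  expect_equal(fr$fraction[fr$program == "p1"], 0.75)
  expect_equal(fr$fraction[fr$program == "p2"], 0)  # empty module, warned
})
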