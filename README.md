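# paleoprog

Tools for two questions about gene regulation in the developing human
cortex: *which gene expression programs switch on, in what order, as neural
progenitors differentiate?* and *which regulatory regions carry
Homo sapiens-specific variants that archaic hominins (Neanderthals,
Denisovans) never acquired — and which transcription factors do those
variants affect?*

The package provides two engines plus a ground-truthed simulator for each:

1. **Pseudotime-informed NMF (piNMF).** Given a non-negative genes x cells
   expression matrix with a per-cell pseudotime (from any upstream
   trajectory tool), piNMF factorizes `Y ~ A X` under non-negativity while
   constraining each temporal pattern (column of `A`) to a smooth
   non-negative spline function of pseudotime: `A = Phi C'`, with `Phi` a
   clamped cubic B-spline basis (4 interior knots by default) and `C >= 0`.
   The solver is hierarchical alternating least squares (HALS; monotone in
   the squared Frobenius objective, tolerance 1e-10, at most 1e4 sweeps).
   Because single NMF fits are non-unique, stable programs are recovered by
   consensus: 750 seeded random restarts, K-means clustering of the
   L2-normalized gene-coefficient vectors, centroids as consensus programs,
   and a constrained refit of the temporal factor. Genes are assigned to
   (semi)discrete modules by per-gene least-squares regression of z-scored
   expression on the program activations with joint Benjamini-Hochberg
   correction. A free-temporal-factor baseline (stdNMF) runs on the same
   machinery so that any difference isolates the spline constraint.

2. **Regulatory islands and TF binding effects.** From a derived-variant
   catalog and an open-chromatin peak atlas (reference peaks kept when >=
   50% covered by a supporting dataset), the pipeline calls *regulatory
   islands*: windows of at least 3 kb centered on variants with derived
   allele frequency >= 90% where archaics carry the ancestral allele, the
   variant sits in open chromatin, and the window contains no archaic
   lineage-specific derived change (overlapping windows merge). Islands are
   linked to genes by GREAT-style regulatory domains (basal 5 kb/1 kb,
   extension up to 1 Mb), tested for enrichment in target region sets
   (selection scans, introgression deserts) by a length- and
   chromosome-matched permutation test (10,000 iterations, +1-corrected
   empirical p), and scanned for allele-specific TF binding changes with an
   information-content PWM score (consensus = 1, anti-consensus = 0), exact
   DP match p-values (threshold 1e-4, uniform background), BH correction,
   a fourth-quartile |delta| filter, and per-TF classification
   (increased / reduced / both) with a strong/total frequency score.

## Worked example

```r
library(paleoprog)

# simulate a bifurcating trajectory with 4 planted programs
sim   <- simulate_bifurcating_expression(n_cells = 300, n_genes = 400, seed = 1)
lineA <- subset_branch(sim$data, "A")          # root cells + branch A
basis <- build_spline_basis(lineA$cells$pseudotime)   # K = 8 cubic basis

cfg  <- factorization_config(rank = 4, mode = "pinmf",
                             n_replicates = 100, base_seed = 1,
                             max_iter = 400, tol = 1e-8)
reps <- run_ensemble(lineA, basis, cfg)
cons <- consensus_programs(lineA, reps, basis = basis)
glance(cons)
#> # A tibble: 1 x 4
#>   mode   rank silhouette frobenius_error
#>   <chr> <int>      <dbl>           <dbl>
#> 1 pinmf     4      0.981            307.

match_programs(cons$activations,
               truth_patterns_for(sim$truth, sim$data, lineA))
#> # A tibble: 4 x 3
#>   program_a program_b correlation
#>   <chr>     <chr>           <dbl>
#> 1 program1  program2        0.998
#> 2 program2  program3        0.978
#> 3 program3  program1        0.994
#> 4 program4  program4        0.999
```

The silhouette (0.98 here) measures how reproducibly the 100 restarts find
the same four components; the matching shows every consensus program
recovers a distinct planted pattern with Pearson r >= 0.97 — including the
transient bump program, which the stdNMF baseline blurs. `autoplot(cons)`
draws the activations along pseudotime; `assign_gene_modules(lineA, cons)`
returns the per-gene module table with q-values.

On the paleogenomic side:

```r
land <- simulate_regulatory_landscape(seed = 1)
isl  <- call_regulatory_islands(land$variants, land$archaic_derived,
                                land$peaks, chrom_sizes = land$chrom_sizes)
nrow(isl)                       # islands found
#> [1] 16
identical(isl$start, land$truth_islands$start)   # matches brute-force truth
#> [1] TRUE
```

A subcommand CLI wraps the same functions for shell pipelines
(`inst/scripts/paleoprog simulate-traj | fit | consensus | assign | atlas |
islands | link | enrich | tfbs | classify`); rerunning any step with the
same seed reproduces its outputs byte for byte.

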