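---
title: "Methods: pseudotime-informed NMF and regulatory-island analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudotime-informed NMF and regulatory-island analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameters and numerical choices behind
the two engines of `paleoprog`: the pseudotime-informed non-negative matrix
factorization (piNMF) used to recover dynamic gene expression programs along
differentiation branches, and the paleogenomic pipeline that calls
"regulatory islands" and scores allele-specific transcription-factor
binding.

## The factorization model

Let $Y$ be a non-negative matrix of normalized log expression with cells as
rows (ordered by pseudotime $t$) and genes as columns. Standard NMF seeks
non-negative factors minimizing $\lVert Y - AX \rVert_F^2$, with $A$ the
temporal ("pattern") factor (cells $\times$ r) and $X$ the gene-coefficient
factor (r $\times$ genes). piNMF additionally constrains every temporal
pattern to be a smooth non-negative function of pseudotime:
$A = \Phi C^\top$, where $\Phi$ is a clamped cubic B-spline basis evaluated
at the cells' pseudotimes and $C \ge 0$ are spline coefficients. Because the
basis functions are non-negative and the coefficients are constrained
non-negative, every temporal pattern is non-negative at all pseudotimes — a
sufficient (not necessary) construction that keeps the subproblem convex.

**Spline basis.** "4 knots" is interpreted as 4 interior breakpoints of a
clamped cubic basis, giving $K = 4 + 3 + 1 = 8$ basis functions. Interior
knots sit at pseudotime quantiles rather than uniform positions, which keeps
each basis function supported by a comparable number of cells when cell
density varies along the trajectory. Rows of $\Phi$ sum to one (partition of
unity); the implementation renormalizes rows to make the invariant exact in
floating point. A basis is only built when the number of distinct
pseudotimes is at least $K$.

**Solver.** Hierarchical alternating least squares (HALS): one sweep updates
each row of $X$ by an exact non-negative block-coordinate step, then each
row of $C$ (piNMF) or column of $A$ (stdNMF) the same way. Every step solves
its one-block subproblem exactly, so the squared-Frobenius objective is
non-increasing sweep by sweep; the trace of objectives is recorded and the
iteration stops when the relative decrease falls below `tol` (default
1e-10) or at `max_iter` (default 1e4) sweeps. Components whose
current scale is numerically zero are left untouched (no division by ~0).
After convergence each temporal pattern is rescaled to unit maximum with
the inverse scale pushed into $X$, leaving $A X$ unchanged; this makes
patterns comparable across replicates and modes. The stdNMF baseline runs
the same machinery with a free temporal factor, so every piNMF-vs-stdNMF
contrast isolates the spline constraint.

**Initialization and replicates.** Factors are initialized elementwise
uniform(0,1]; replicate $i$ of an ensemble is seeded `base_seed + i`, making
ensembles bitwise reproducible. The default ensemble size is 750 replicates
per rank.

## Consensus programs

NMF solutions are non-unique, so stable programs are recovered by
clustering: the $r$ rows of $X$ from every replicate are L2-normalized and
pooled, K-means with Euclidean distance and $k = r$ clusters them, and the
cluster centroids become the consensus gene-coefficient matrix. Clustering
operates on gene coefficients rather than temporal patterns — the two are
interchangeable in principle; gene-coefficient space is used because the
gene dimension is typically much larger and discriminates components more
sharply. The consensus temporal factor is then recovered by a single
non-negative least-squares refit against the consensus coefficients —
under the spline constraint for piNMF replicates (so consensus patterns
remain smooth functions of pseudotime), free for stdNMF. Empty K-means
clusters trigger up to 10 re-initializations before erroring. No replicate
filtering is applied by default.

Stability is summarized by the mean silhouette width of the clustered
component vectors and error by the Frobenius norm of
$Y - A_{\text{cons}} X_{\text{cons}}$. For presentation, each consensus
pattern is min-max scaled across cells to $[0,1]$ ("activation"); constant
columns cannot be scaled and are returned as zeros with a warning.

**Rank selection.** `rank_sweep()` reports silhouette and Frobenius error
across candidate ranks. A caution discovered while validating on synthetic
data: when a strong solver meets clean low-rank data, the fits *below* the
true rank converge to a unique merged optimum from almost every restart, so
their silhouette is exactly 1 and the silhouette argmax can sit below the
true rank. Stability should therefore be read together with the error curve
(the error stops improving past the true rank), not as a single argmax.

## Gene module assignment

Each gene's expression is z-scored across the analyzed cells and regressed
by ordinary least squares on the $r$ activation columns; the response is
centered, so no intercept is included (an intercept would also be nearly
collinear with sequential programs whose activations sum to roughly one at
every cell). Per-coefficient two-sided t-tests are Benjamini–Hochberg
corrected jointly across all gene $\times$ program tests; a gene belongs to
every module with $q < \alpha$ (default 0.05) and a positive coefficient,
so modules are "semi-discrete" — genes may belong to several. Zero-variance
genes are dropped with a message. Module agreement between two runs uses an
asymmetric convention, the percentage of the reference module recovered in
the other ($100\,|A\cap B|/|A|$), after pairing programs by maximal
activation correlation.

## The synthetic trajectory generator

The generator plants a known bifurcating structure: pseudotime uniform on
$[0,1]$, a branch point at 0.5 (cells before it labelled `root`, after it
`A` or `B`, allocated in balanced halves), and `n_programs` (default 4)
temporal programs per lineage: an early program declining from the root, a
transient Gaussian bump near the bifurcation, intermediate windowed
programs, and a terminal program that switches on last and stays on.
Programs tile pseudotime in roughly equal-power windows with sequential
handoff; transition widths are broad enough that every pattern lies close
to the non-negative spline cone of the default basis. Both choices are
deliberate identifiability conditions: heavily overlapping late sigmoids
make the planted rank-4 decomposition non-identifiable for any NMF, and
patterns far outside the spline cone would conflate model error with
solver error.

Each gene loads on one primary program (Gamma-distributed loading), 20%
also on a secondary program at half weight. Expression is
`loadings x patterns` degraded by three artifacts: entry-wise lognormal
noise (`noise_sd`, default 0.25), a per-cell lognormal scale factor
(`cell_noise_sd`, default 0.35) emulating residual library-size variation
after normalization, and Bernoulli dropout (default 0.2). The per-cell
factor is the feature that separates the two factorization modes: a free
temporal factor absorbs it cell by cell, while the spline-constrained
factor cannot chase it — which is precisely why piNMF resolves the
transient program more faithfully on these data. Defaults are 1000 cells
and 2000 features.

What the generator does **not** emulate: count statistics (no Poisson or
negative-binomial sampling, no depth differences), doublets, batch effects,
or correlated gene-gene noise. Passing the recovery benchmarks therefore
shows the algorithms behave as designed under their own model class plus
moderate multiplicative noise, not that they are robust to every artifact
of real scRNA-seq data. A further honest caveat found during validation:
for roughly one simulated dataset in ten, the global optimum of the noisy
rank-4 objective is *not* the planted decomposition (splitting the
high-energy early program pays more than modeling the weakest windowed
program), and the replicate majority — hence the consensus — follows that
basin. This is a property of the estimation problem, not of the
implementation.

**Benchmark scales.** The test suite and acceptance script fit consensus
benchmarks at 300 cells x 400 genes (240 x 300 for rank sweeps) with
15-100 replicates, sizes chosen as the smallest at which recovery is
stable; the noiseless exact-factorization check runs at the full
1000 x 2000 scale.

## Regulatory islands

The paleogenomic engine takes as given: a variant catalog (ancestral and
derived alleles, derived-allele frequency, the archaic genotype state), the
positions where archaic genomes carry lineage-specific derived alleles,
open-chromatin peak sets, and target region sets. Coordinates are BED-style
0-based half-open throughout; variant TSVs carry 1-based positions on disk
and are converted on load.

**Peak atlas.** A reference peak is retained when at least 50% of its
length is covered by the merged intervals of at least one supporting
dataset; chrX/chrY intervals from dedicated sources are appended verbatim
and flagged, since the reference assay lacks sex-chromosome signal.

**Island definition.** A variant qualifies when its derived-allele
frequency is $\ge$ 0.9 (inclusive), archaics carry the ancestral allele
(missing genotypes are conservatively non-qualifying), the variant lies
inside an atlas peak (a peak merely overlapping the window does not
qualify it), and the centered window $[pos - 1500, pos + 1500)$ fits
entirely inside the chromosome and contains no archaic lineage-specific
derived position. Windows truncated by a chromosome end are rejected
rather than trimmed, because the definition demands at least 3000 bp.
Overlapping qualifying windows merge into one island with pooled member
variants. The toy-landscape simulator recomputes the truth set by an
independent brute-force scan, and the caller is required (in tests) to
match it exactly on a thousand random landscapes.

**Gene linking.** GREAT-style regulatory domains: a basal domain per TSS
(5 kb upstream, 1 kb downstream, strand-aware) extended each way up to the
nearest neighboring basal domain, at most 1 Mb, clipped to the chromosome;
an island links to every gene whose domain it overlaps. Curated domains,
when available, take precedence for their genes.

**Permutation test.** The statistic is the number of query regions
overlapping at least one target region. The null redraws regions of
identical lengths on their original chromosomes uniformly at random
(overlaps among placed regions are allowed — the simplest exchangeable
null; an optional exclusion mask is honored by redraw). The empirical
p-value uses the +1 correction, $(1 + \#\{null \ge obs\})/(1 + n_{perm})$,
so it is never zero; 10,000 permutations by default. Because the statistic
is a bounded count, its p-values are discrete; calibration checks use
enough query regions that the discretization is mild.

## TF binding-affinity effects

PWMs are parsed from JASPAR/HOCOMOCO-style text, pseudocount-regularized
(0.8 per position, split evenly across bases) and normalized. A sequence's
match score is the information-content sum $\sum_i p_i(s_i)$, min-max
scaled so the consensus scores 1 and the anti-consensus 0. Exact match
p-values come from a dynamic-programming convolution of per-position score
distributions under a uniform (configurable) background; the DP uses an
internal per-position grid of $10^{-4}/L$ of the scaled range so the
accumulated rounding stays within one user-facing $10^{-4}$ bin, verified
against exhaustive enumeration for motif lengths up to 8. Degenerate
motifs whose sequences all tie are assigned score 0 and p-value 1.

For each variant and motif, all windows covering the variant are scanned on
both strands for the ancestral and derived allele; the single
(offset, strand) with the best better-allele score is kept per motif, an
effect is emitted when that allele's match p-value is $\le 10^{-4}$,
p-values are BH-corrected jointly across emitted motif x variant tests,
and only the best effect per TF and variant survives (redundant motifs
dropped). Effects are `strong` when their absolute affinity difference
falls in the fourth (top) quartile of the |delta| distribution; a TF is
classed `increased`/`reduced` when all its strong effects move one way,
`both` when mixed, `none` otherwise, with frequency score = strong/total
hits. This scoring is an independent implementation of the
information-content idea; exact numerical agreement with any particular
motif-disruption tool is not claimed.

## Reproducibility

All randomness flows from explicit seeds: replicate $i$ uses
`base_seed + i`, the consensus K-means has its own fixed seed, and every
CLI output embeds the configuration. Rerunning any pipeline with the same
config and seed reproduces output files byte for byte, which the test
suite asserts.

## Known limitations

- Consensus follows the replicate majority; when a spurious basin of the
  objective dominates (see above), more replicates do not rescue it.
- Silhouette-based rank selection is biased toward small ranks on clean
  data; use it jointly with the error curve.
- The permutation null is length- and chromosome-matched but ignores GC,
  gap and accessibility structure of real genomes.
- PWM scanning assumes single-nucleotide variants in unambiguous (ACGT)
  context sequence.
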