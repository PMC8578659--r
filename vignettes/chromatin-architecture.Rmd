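---
title: "Methods: chromatin-architecture statistics on cis Hi-C maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-architecture statistics on cis Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicarch)
```

# Scope and data model

`hicarch` operates on **cis** (single-chromosome) contact matrices at a
fixed bin size — the resolutions used in practice are 10 kb (loops), 40 kb
(insulation, TAD and boundary aggregates), 150 kb (region-set contact
enrichment) and 500 kb (compartments). Coordinates are 0-based and
half-open throughout: bin *b* (1-based R index) covers
`[start_bp + (b-1)*bin_size, start_bp + b*bin_size)`. Region sets are
`GRanges`; chromosome names pass through verbatim, and a name mismatch
between a matrix and a region set is an error rather than a silent empty
join. Trans contacts, multi-resolution stores and binary Hi-C formats are
out of scope.

A `ContactMatrix` carries its transform state (`raw`, `balanced`, `oe`,
`pcc`) and a per-bin mask. Bins with a zero raw marginal are masked before
balancing (the balancing fixed point is undefined on zero marginals), and
masked bins are `NA` in every transformed kind and excluded from every
mean.

# Matrix transforms

**Depth matching.** Cross-condition comparisons of raw contacts are only
meaningful at equal depth, so `downsample_counts()` draws the target
number of read pairs *without replacement* from the multiset of observed
pairs (multivariate hypergeometric, realized as sequential conditional
hypergeometric draws over cells). The upper-triangle total is conserved
exactly, and the seed is a mandatory argument.

**Balancing.** `kr_balance()` finds weights `x` with
`diag(x) M diag(x)` having equal (unit) row sums on unmasked bins. The
iteration is the symmetric scaling `x <- x / sqrt(rowsum)`; its fixed
point is the same doubly-balanced matrix that Knight–Ruiz or Sinkhorn
iteration reaches, which is the contract (the algorithmic path is not).
Convergence is declared on the coefficient of variation of row sums
(default tolerance `1e-6`, cap 3000 iterations); non-convergence is an
error that reports the final residual. The test suite checks entrywise
agreement (< 1e-8) with an independent alternating-Sinkhorn oracle.

**O/E.** The expected value at distance *d* is the arithmetic mean of the
defined entries on diagonal *d* of the same chromosome — per-diagonal
means, unsmoothed. Smoothing expected values at long range (where
diagonals are short and noisy) is a known variant; we deliberately use raw
means because they are exactly testable (each output diagonal has mean 1)
and flag the sensitivity in *Limitations*. Diagonals with no defined
entries, or zero mean, become `NA` rather than 0.

**PCC.** Row-vector Pearson correlation over mutually defined positions.
With undefined entries present this is computed by an exact
pairwise-complete formulation in matrix products (O(n³) overall rather
than per-pair), verified against the textbook formula in the tests.
Zero-variance rows are `NA`.

# Compartments

PC1 is the unit-norm leading principal-component loading of the
column-centered PCC matrix. The global sign is then fixed by the GC
convention: A (active) chromatin is GC-rich, so the eigenvector is flipped
iff mean GC over negative-PC1 bins exceeds mean GC over positive-PC1
bins. Short-range diagonal entries are *not* excluded before the PCA (the
tooling this mirrors is silent on the point, and excluding them changes
nothing at 500 kb in our recovery tests).

The saddle map splits defined bins into five PC1 groups — minimum to 20th
percentile, and so on. Group assignment is rank-based with ties broken by
stable bin order, so group sizes are as equal as `n` allows. Cell (a, b)
is the mean O/E over all defined entries with bins in groups a and b.

Compartment strength is `ln((AA·BB)/AB²)` with **AA = sum of saddle rows
1–3 × columns 1–3 and BB = rows 3–5 × columns 3–5** — the two blocks
deliberately share the middle quintile, exactly as the convention this
package reproduces defines them; users comparing against corner-only
conventions should expect slightly compressed values. AB is printed
ambiguously in that convention ("rows 1–3 (rows 3–5) and columns 3–5
(columns 1–3)"); we read it as the mean of the two symmetric off-blocks,
which keeps AA, BB and AB on the same 9-cell scale (and the two blocks are
equal on any symmetric map). The bootstrap resamples, for each saddle
cell, its contributing O/E values with replacement at the same size, and
recomputes the strength; 100 replicates is the convention. We resample
per-cell contributor values, not bins, following the stated construction
("all the values that contributed to this pixel").

# Insulation and boundary aggregates

For bin *i* the raw insulation is the mean O/E in the square window rows
`i−w…i−1` × columns `i+1…i+w` (default `w = 5` bins at 40 kb); bins whose
window leaves the matrix are undefined. Normalization divides by the mean
raw score of the **50 nearest bins — read as 25 on each side of *i*,
excluding *i* itself, shrinking at the track ends** (the source convention
does not say centered vs one-sided; centered is the symmetric choice) and
log2-transforms. Boundaries are local minima of the normalized track
(`call_boundaries()`: minimum over a ±2-bin neighborhood, below 0).

Boundary aggregates center a 2 Mb window — read as **1 Mb of flank on each
side** of the element's 5′ end — on stranded elements at 40 kb (51×51
cells); minus-strand submaps are flipped on both axes before averaging, so
the aggregate is 5′→3′ oriented. Elements spanning several bins anchor at
the bin containing the 5′ end. Undefined cells are excluded from per-cell
averages with per-cell contributor counts kept. The optional row z-scoring
acts on the log2 aggregate.

# TAD and loop aggregates

Each domain of length L contributes its 3L-wide submap (start−L to
end+L), resampled to 90×90 pixels: exact block-averaging with fractional
edge weights when the source is larger, bilinear interpolation on bin
centers when smaller. Block-averaging preserves the mean of
block-constant inputs exactly (a test asserts this). TAD strength is the
sum of the central 30×30 block over half the sum of the two flanking
blocks `[0:30, 30:60]` and `[30:60, 60:90]` (0-based half-open).

Loop pileups average 31×31-bin windows (310 kb at 10 kb) centered on the
anchor-pair bins. The loop-strength scoring square is **3×3 bins** (the
"31 × 31 kb" square at 10 kb bins — the two printed sizes differ by 10×
because one is the pileup window and one the scoring square). The control
is the mean over the two positions offset diagonally by the loop length
(±L on both anchors, preserving anchor distance), using whichever offsets
are on-matrix; the direction of the offset is not stated in the source
convention, so both are computed and the headline is their mean
(`loop_strength(..., detail = TRUE)` reports each).

# Region enrichment

Contact values are taken from the O/E matrix at 150 kb by default (any
`ContactMatrix` kind is accepted). `contacts_within()` returns the values
of all defined pairs i < j with both bins in the set;
`contacts_between()` all pairs with one bin in the focal interval and one
in the set, excluding within-focal pairs. The null model draws region
sets preserving the number and length multiset of the template, placed
uniformly on the *same chromosome* (the analyses are cis), non-overlapping
within a replicate and avoiding masked bins. Each of the N = 10
replicates yields a two-sided Mann–Whitney U p-value against the observed
values, and the replicate p-values are averaged — the observed-vs-each-
replicate design, not a pooled null. p-values are floored at the smallest
representable double, so an underflowed p prints as ~5e-324, never 0.

`mann_whitney_u()` computes U from midranks; the p-value is exact (null
U distribution) when `n·m ≤ 400` without ties, otherwise a normal
approximation with tie and continuity corrections. Type-I error is
simulation-checked at α = 0.05.

`pcc_difference()` and `contacts_log2fc()` compare two conditions on the
same frame over the same pair sets, dropping pairs undefined in either
matrix; matrices should be depth-matched with `downsample_counts()` first
(the CLI `log2fc` subcommand does this automatically, to the smaller
total).

# Stage specificity

The specificity score of a gene with stage profile `x` is
`1 − H(p)/log2(K)` where `p = x / sum(x)` and `H` is Shannon entropy in
bits: 1 for one-hot, 0 for uniform, 0.5 for a two-stage half-half profile
over four stages. The underlying entropy measure is cited in the source
convention without a formula; this normalized form is the standard
entropy-based specificity, and a `log_transform` flag computes it on
`log2(TPM+1)` instead of raw TPM for users who want the damped variant.

Genes with score > 0.2 are clustered on row-standardized `log2(TPM+1)`
profiles with K-means, k = 4. The design calls for k-means++
initialization with 50 restarts; we use base R's Hartigan–Wong with
`nstart = 50` random restarts instead — the contract (best-inertia
solution under a fixed seed) is the same and no k-means++ implementation
is available in the dependency envelope. Clusters are relabeled C1…Ck by
the stage of their centroid peak, earliest first, so "C1" is the
earliest-stage cluster deterministically. Shift tests compare each
cluster's `log2(TPM+1)` treated-minus-control shifts against all genes
with the same Mann–Whitney machinery.

# The synthetic generator: what a green test establishes

`simulate_hic()` composes an expected matrix multiplicatively on a
power-law decay `(d+1)^−α` (α = 1 by default, the canonical cis decay
slope at sub-Mb to Mb scales): same-compartment pairs ×√c and
cross-compartment ×1/√c (so the planted within/between O/E ratio is
exactly the `compartment_contrast` c, and c = 1 is exactly
structureless); within-TAD pairs × their contrast; 3×3 anchor patches ×
loop enrichment; within-block pairs × the PNH contrast; focal-to-block
pairs × the focal contrast. Counts are Poisson on the upper triangle,
mirrored (a negative-binomial flag is deliberately absent: at matched
depth the extra-Poisson variance of real Hi-C is dominated by the
systematic biases that balancing removes, and the recovery tests are about
statistical machinery, not error models). Defaults follow the desk-scale
frames used by the tests: 600 bins × 150 kb (a 90 Mb pseudo-chromosome,
~3 Mb compartment blocks, depth 2 × 10⁶ giving ≳ 250 counts/bin on the
first off-diagonal) for compartment and enrichment tests; 400–440 bins ×
40 kb with 20-bin TADs and depth 10⁶ for insulation; 600 bins × 10 kb for
loops.

What the generator does **not** emulate: restriction-fragment and
mappability bias (so balancing weights are near-uniform except where
structure is planted), distance-dependent overdispersion, translocations
or copy-number steps, unmappable regions (masks arise only from sampling
zeros), and any coupling between expression and contact structure. A
green recovery test therefore establishes that the *statistics* recover
planted structure at realistic depth — not that the pipeline is robust to
every artifact of real libraries.

One behavior of real data the generator *does* reproduce and that users
should know: matrix balancing partially absorbs strong localized
enrichment into the coverage weights, because a heavily enriched block
raises its rows' marginals. Planted contrasts are recovered exactly on
the O/E of the raw matrix, and as relative (within vs like-distance
background) enrichment after balancing; the TAD/loop/compartment strength
statistics are ratios and remain monotone in the planted contrast either
way (a property the acceptance suite asserts over a contrast grid).

# Numerical conventions and degenerate inputs

* Quantile-group ties: stable bin order (deterministic saddle).
* `orient_by_gc()` on a single-signed PC1: returned unchanged with a
  warning flag.
* AB = 0, all-zero matrices, empty region sets, < 5 defined bins for a
  saddle, fewer passing genes than k: all errors, never silent NA.
* All stochastic stages (downsampling, null regions, bootstrap, K-means,
  simulation) take explicit seeds and are byte-reproducible; the CLI
  writes a provenance JSON (inputs, parameters, seeds, version; no
  timestamps) next to every output.
* p-values are never printed as 0 (floored at `.Machine$double.xmin`).

# Limitations

* Expected values are unsmoothed per-diagonal means; at very long range
  (short diagonals) O/E is noisy, and an expected-value smoother would be
  the first extension for chromosome-arm-scale work.
* The saddle's AA/BB blocks share the middle quintile by design fidelity;
  absolute strengths are therefore not comparable to corner-only
  implementations (ordering and monotonicity are).
* Only cis matrices are modeled; the headline statistics of the study
  this package generalizes (e.g. specific p-values on deposited mES-cell
  data) require those datasets and are outside the desk-scale test
  surface.
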