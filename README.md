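# hicarch

Chromatin-architecture statistics for cis Hi-C contact maps.

`hicarch` is for epigenomics analysts who want to compare higher-order
chromatin organization between two conditions — e.g. asking whether a
repressive hub such as the peri-nucleolar heterochromatin (PNH) loses
internal contacts after a perturbation, or whether a focal locus (a
*Dux*-like 2-cell-program gene) detaches from that hub. It implements the
statistics this kind of study runs downstream of read mapping, on plain
single-chromosome contact matrices:

* **Matrix transforms** — read-pair downsampling to a common depth
  (multivariate hypergeometric), Knight–Ruiz-style balancing,
  observed/expected (O/E) by per-diagonal means, and the Pearson-correlation
  (PCC) matrix.
* **A/B compartments** — PC1 of the PCC matrix, GC-content sign
  orientation, the 5×5 PC1-quintile saddle map, and compartment strength
  `ln((AA·BB)/AB²)` with a per-cell bootstrap (AA = saddle rows/cols 1–3,
  BB = rows/cols 3–5, AB = the symmetric off-blocks).
* **Insulation and TAD boundaries** — windowed insulation score
  (5-bin square window upstream×downstream of each bin), normalized against
  the nearest 50 bins and log2-transformed; boundaries = local minima.
  Oriented aggregate maps around stranded elements (e.g. MERVL repeats).
* **TAD / loop aggregates** — domain pileups rescaled to 90×90 pixels with
  within/between strength, and 31×31-bin loop pileups with loop strength
  against diagonally offset controls.
* **Region enrichment** — contact density within a region set, or between
  a focal locus and a set, compared against N = 10 random region sets
  matched for number and length (two-sided Mann–Whitney U per replicate,
  averaged p), plus PCC differences and contact log2 fold-changes between
  conditions.
* **Stage specificity** — entropy-based specificity score
  `1 − H(p)/log2(K)` for genes × developmental-stages TPM tables, K-means
  staging clusters C1–C4, and per-cluster expression-shift tests.
* **Synthetic data** — a generator planting compartments, TADs, loops, a
  PNH-like block and a focal locus on a power-law-decay Poisson contact
  map, plus stage-patterned expression with planted clusters. Every
  statistic above is verified by recovering what was planted.

## Worked example

Simulate a 300-bin (45 Mb at 150 kb) chromosome with a planted A/B
checkerboard at within/between contrast 1.6, then recover it:

```r
library(hicarch)
sim <- simulate_hic(simulation_spec(n_bins = 300, compartment_contrast = 1.6,
                                    depth = 1e6, seed = 42))
oe  <- observed_expected(kr_balance(sim$matrix))
pc1 <- orient_by_gc(compute_pc1(pearson_correlation_matrix(oe)), sim$gc)
mean(sign(pc1$values) == sim$truth$compartment_labels, na.rm = TRUE)
#> [1] 1
s <- saddle(oe, pc1)
s
#> <SaddleMap> 5 x 5 mean O/E
#>       [,1]  [,2]  [,3]  [,4]  [,5]
#> [1,] 1.233 1.162 0.948 0.814 0.801
#> [2,] 1.162 1.095 0.962 0.870 0.810
#> [3,] 0.948 0.962 1.026 1.032 1.055
#> [4,] 0.814 0.870 1.032 1.132 1.195
#> [5,] 0.801 0.810 1.055 1.195 1.221
compartment_strength(s, n_boot = 100, seed = 1)
#> <CompartmentStrength> ln(AA*BB/AB^2) = 0.3111  (bootstrap sd 0.0041, n = 100)
```

Every bin's PC1 sign matches the planted compartment label; the saddle's
like-with-like corners are enriched (O/E ≈ 1.2) and the A-with-B corners
depleted (≈ 0.8), giving a positive strength with a tight bootstrap. A
structureless map (contrast 1.0) gives strength ≈ 0.

The Mann–Whitney helper reproduces textbook exact cases:

```r
mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#> $U
#> [1] 0
#> $p
#> [1] 0.1
```

A command-line surface mirrors the R API
(`Rscript -e 'hicarch::hic_cli()' simulate --seed 7 --out sim`, then
`balance`, `oe`, `pc1`, `saddle`, `compartment-strength`, `insulation`,
`tad-strength`, `loop-strength`, `pnh-enrich`, `pcc-diff`, `log2fc`,
`stage-score`, `stage-cluster`, `shift-test`; see `?hic_cli`). Every run
writes a JSON provenance record and is byte-reproducible given its seed.

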