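test_that("contacts_within / contacts_between enumerate the right pairs", {
  n <- 30
  bs <- 150000
  u <- contact_matrix(matrix(1, n, n), "chrT", bs, kind = "oe")
  all_gr <- gr0("chrT", 0, n * bs)

  # regions covering all bins -> all upper-triangle (i < j) values
  vals <- contacts_within(u, all_gr)
  expect_length(vals, n * (n - 1) / 2)
  expect_equal(mean(vals), 1)

  # planted block enrichment 2.0: mean matches brute-force enumeration
  block <- 10:17
  v <- matrix(1, n, n)
  v[block, block] <- 2
  m <- contact_matrix(v, "chrT", bs, kind = "oe")
  gr_block <- bins_to_gr(m, block)
  vals <- contacts_within(m, gr_block)
  ref <- c()
  for (i in block) for (j in block) if (i < j) ref <- c(ref, v[i, j])
  expect_equal(sort(vals), sort(ref))
  expect_equal(mean(vals), 2)

  # focal inside regions: consistency with the within restriction
  focal <- bins_to_gr(m, 1:3)
  bet <- contacts_between(m, focal, all_gr)
  ref <- c()
  for (i in 1:3) for (j in 4:n) ref <- c(ref, v[i, j])
  expect_equal(sort(bet), sort(ref))

  # chromosome mismatch is an error, not an empty join
  expect_error(contacts_within(m, gr0("chrZ", 0, 1e6)), "chrZ")
  expect_error(contacts_within(m, bins_to_gr(m, 5)), "fewer than 2")
})

test_that("sample_random_regions preserves lengths and is deterministic", {
  template <- c(gr0("chrT", 1e6, 2.5e6), gr0("chrT", 5e6, 5.6e6),
                gr0("chrT", 8e6, 8.3e6))
  sizes <- c(chrT = 45e6)
  reps <- sample_random_regions(template, sizes, n_replicates = 5, seed = 3)
  expect_length(reps, 5)
  for (r in reps) {
    expect_equal(sort(GenomicRanges::width(r)),
                 sort(GenomicRanges::width(template)))
    # non-overlapping within a replicate
    expect_equal(length(GenomicRanges::reduce(r)), length(r))
  }
  # determinism
  reps2 <- sample_random_regions(template, sizes, n_replicates = 5, seed = 3)
  expect_identical(lapply(reps, as.data.frame), lapply(reps2, as.data.frame))

  # forced placement: a one-interval-sized chromosome returns the interval
  tpl <- gr0("chrT", 0, 1e6)
  out <- sample_random_regions(tpl, c(chrT = 1e6), n_replicates = 2,
                               seed = 1)
  for (r in out) {
    expect_equal(GenomicRanges::start(r), 1)
    expect_equal(GenomicRanges::end(r), 1e6)
  }

  # impossible placement errors
  expect_error(
    sample_random_regions(gr0("chrT", 0, 2e6), c(chrT = 1e6), 1, seed = 1),
    "shorter")
})

test_that("mann_whitney_u matches exact enumeration and wilcox.test", {
  # the exact no-overlap case: p = 2/C(6,3) = 0.1
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)

  # identical samples -> p = 1 (within the tie approximation)
  mw <- mann_whitney_u(rep(1:5, 4), rep(1:5, 4))
  expect_gt(mw$p, 0.9)

  # agreement with wilcox.test on random data, exact branch
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(11, 0.5)
    mw <- mann_whitney_u(x, y)
    wt <- wilcox.test(x, y, exact = TRUE, correct = TRUE)
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-12)
  }
  # approximate branch (large n, ties)
  for (i in 1:5) {
    x <- sample(1:10, 40, replace = TRUE)
    y <- sample(1:10, 45, replace = TRUE)
    mw <- mann_whitney_u(x, y)
    wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-9)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("mann_whitney_u type-I error is calibrated", {
  set.seed(1234)
  n_sim <- 1000
  rej <- 0
  for (i in seq_len(n_sim)) {
    x <- rnorm(25); y <- rnorm(25)
    if (mann_whitney_u(x, y)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_sim, 0.035)
  expect_lte(rej / n_sim, 0.065)
})

test_that("enrichment_test composes observed, nulls and averaged p", {
  n <- 200
  bs <- 150000
  sizes <- c(chrT = n * bs)
  block <- 60:79
  v <- matrix(1, n, n) + matrix(rnorm(n * n, 0, 0.01), n, n)
  v <- (v + t(v)) / 2
  v[block, block] <- v[block, block] + 1
  m <- contact_matrix(v, "chrT", bs, kind = "oe")
  regions <- bins_to_gr(m, block)

  res <- enrichment_test(m, regions, chrom_sizes = sizes,
                         n_replicates = 3, seed = 9)
  expect_length(res$p_values, 3)
  expect_equal(res$p_mean, mean(res$p_values))
  expect_true(all(res$p_values > 0 & res$p_values <= 1))
  expect_equal(res$direction, 1)
  expect_lt(res$p_mean, 0.01)

  # n_replicates = 1: p_mean is the single p
  res1 <- enrichment_test(m, regions, chrom_sizes = sizes,
                          n_replicates = 1, seed = 9)
  expect_equal(res1$p_mean, res1$p_values[1])

  # determinism under a fixed seed
  res2 <- enrichment_test(m, regions, chrom_sizes = sizes,
                          n_replicates = 3, seed = 9)
  expect_identical(res$p_values, res2$p_values)
})

test_that("pcc_difference and contacts_log2fc match enumeration", {
  n <- 40
  bs <- 150000
  a <- random_kind_cm(n, seed = 4, kind = "pcc", bin_size = bs)
  b <- random_kind_cm(n, seed = 5, kind = "pcc", bin_size = bs)
  xb <- 5:10
  yb <- 25:32
  sx <- bins_to_gr(a, xb)
  sy <- bins_to_gr(a, yb)

  expect_equal(pcc_difference(a, a, sx, sy), 0)
  expect_equal(pcc_difference(a, b, sx, sy),
               pcc_diff_oracle(a$values, b$values, xb, yb),
               tolerance = 1e-12)

  # constant-pair case
  ca <- a; ca$values[xb, yb] <- 0.8; ca$values[yb, xb] <- 0.8
  cb <- b; cb$values[xb, yb] <- 0.3; cb$values[yb, xb] <- 0.3
  expect_equal(pcc_difference(ca, cb, sx, sy), 0.5, tolerance = 1e-12)

  # log2 fold change: identical matrices -> 0; doubled -> 1
  oa <- random_kind_cm(n, seed = 6, kind = "oe", bin_size = bs)
  ob <- oa
  gene_sets <- list(gsA = sy)
  tab <- contacts_log2fc(oa, ob, sx, gene_sets)
  expect_equal(tab$log2fc, 0)
  ob$values <- oa$values / 2
  tab <- contacts_log2fc(oa, ob, sx, gene_sets)
  expect_equal(tab$log2fc, 1, tolerance = 1e-12)
})
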