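test_that("downsample_counts conserves the target exactly and is unbiased", {
  m <- random_raw_cm(12, seed = 1, lambda = 40)
  total <- sum(m$values[upper.tri(m$values, diag = TRUE)])

  # identity case
  expect_identical(downsample_counts(m, total, seed = 5)$values, m$values)

  # forced conservation on a single-cell matrix
  tiny <- contact_matrix(matrix(c(0, 10, 10, 0), 2), "chrT", 40000)
  for (seed in c(1, 99)) {
    ds <- downsample_counts(tiny, 4, seed)
    expect_equal(sum(ds$values[upper.tri(ds$values, diag = TRUE)]), 4)
  }

  # exact conservation, nonnegativity, symmetry on a bigger matrix
  ds <- downsample_counts(m, floor(total / 3), seed = 7)
  expect_equal(sum(ds$values[upper.tri(ds$values, diag = TRUE)]),
               floor(total / 3))
  expect_true(all(ds$values >= 0))
  expect_lt(max(abs(ds$values - t(ds$values))), 1e-9)
  expect_true(all(ds$values <= m$values))

  # insufficient depth errors
  expect_error(downsample_counts(m, total + 1, seed = 1), "insufficient")
})

test_that("downsample_counts matches hypergeometric moments (Monte-Carlo)", {
  # 3x3 matrix, target half the pairs; 5000 draws (spec design uses 10000;
  # halved for runtime, same 3-standard-error check)
  v <- matrix(c(8, 4, 2, 4, 6, 3, 2, 3, 10), 3)
  m <- contact_matrix(v, "chrT", 40000)
  counts <- v[upper.tri(v, diag = TRUE)]
  total <- sum(counts)
  target <- total %/% 2
  n_mc <- 5000
  acc <- matrix(0, n_mc, length(counts))
  for (s in seq_len(n_mc)) {
    ds <- downsample_counts(m, target, seed = s)
    acc[s, ] <- ds$values[upper.tri(ds$values, diag = TRUE)]
  }
  exp_mean <- counts * target / total
  hyper_var <- counts * (target / total) * (1 - target / total) *
    (total - counts) / (total - 1)
  se <- sqrt(hyper_var / n_mc)
  expect_true(all(abs(colMeans(acc) - exp_mean) <= 3 * se))
})

test_that("kr_balance reaches the doubly-balanced fixed point", {
  # already balanced up to scale
  b <- kr_balance(contact_matrix(matrix(c(0, 2, 2, 0), 2), "chrT", 40000))
  expect_equal(b$values, matrix(c(0, 1, 1, 0), 2), tolerance = 1e-9)

  # 2x2 against the Sinkhorn oracle
  m <- contact_matrix(matrix(c(2, 1, 1, 3), 2), "chrT", 40000)
  b <- kr_balance(m, tol = 1e-12)
  expect_lt(max(abs(rowSums(b$values) - 1)), 1e-10)
  expect_lt(max(abs(b$values - sinkhorn_oracle(m$values))), 1e-8)

  # zero-marginal bin masked, remaining submatrix balanced
  v <- matrix(c(2, 0, 1, 0, 0, 0, 1, 0, 3), 3)
  b <- kr_balance(contact_matrix(v, "chrT", 40000), tol = 1e-10)
  expect_true(b$mask[2])
  expect_true(all(is.na(b$values[2, ])))
  expect_equal(rowSums(b$values[c(1, 3), c(1, 3)]), c(1, 1),
               tolerance = 1e-8)

  # error paths
  expect_error(kr_balance(contact_matrix(matrix(0, 3, 3), "chrT", 40000)),
               "zero")
  expect_error(kr_balance(random_raw_cm(10, 1), max_iter = 1),
               "converge")
})

test_that("kr_balance row-sum CV meets tol on random matrices", {
  for (seed in 1:5) {
    m <- random_raw_cm(25, seed, lambda = 50)
    b <- kr_balance(m, tol = 1e-8)
    keep <- !b$mask
    rs <- rowSums(b$values[keep, keep])
    expect_lt(sd(rs) / mean(rs), 1e-8)
    expect_lt(max(abs(b$values - t(b$values)), na.rm = TRUE), 1e-9)
  }
})

test_that("observed_expected divides by per-diagonal means", {
  # constant along each diagonal -> all ones
  n <- 6
  v <- outer(seq_len(n), seq_len(n), function(i, j) 10 / (abs(i - j) + 1))
  oe <- observed_expected(contact_matrix(round(v), "chrT", 40000))
  expect_equal(oe$values, matrix(1, n, n), tolerance = 1e-12)

  # mixed values match the brute-force oracle; per-diagonal mean = 1
  m <- random_raw_cm(9, seed = 3, lambda = 20)
  oe <- observed_expected(kr_balance(m, tol = 1e-10))
  expect_equal(oe$values, oe_oracle(kr_balance(m, tol = 1e-10)$values),
               tolerance = 1e-9)
  for (d in 0:7) {
    i <- seq_len(9 - d)
    vals <- oe$values[cbind(i, i + d)]
    if (any(!is.na(vals))) expect_equal(mean(vals, na.rm = TRUE), 1,
                                        tolerance = 1e-9)
  }

  # empty (all-undefined) diagonal stays NA, not 0
  b <- contact_matrix(matrix(c(0, 3, 2, NA, 3, 0, 3, 2, 2, 3, 0, 3,
                               NA, 2, 3, 0), 4),
                      "chrT", 40000, kind = "balanced")
  oe <- observed_expected(b)
  expect_true(is.na(oe$values[1, 4]))
})

test_that("pearson_correlation_matrix matches the textbook formula", {
  # identical rows give 1, mirrored rows give -1
  v <- matrix(c(1, 9, 3, 4,
                9, 1, 7, 6,
                3, 7, 5, 2,
                4, 6, 2, 8), 4, byrow = TRUE)
  pcc <- pearson_correlation_matrix(contact_matrix(v, "chrT", 40000,
                                                   kind = "oe"))
  expect_equal(pcc$values[1, 2], -1, tolerance = 1e-12)  # row2 = 10 - row1
  expect_equal(diag(pcc$values), rep(1, 4))

  # random O/E vs direct pairwise formula (with and without NAs)
  m <- random_kind_cm(6, seed = 11, kind = "oe")
  pcc <- pearson_correlation_matrix(m)
  expect_equal(pcc$values, pcc_oracle(m$values), tolerance = 1e-9)

  m$values[1, 6] <- m$values[6, 1] <- NA
  pcc <- pearson_correlation_matrix(m)
  expect_equal(pcc$values, pcc_oracle(m$values), tolerance = 1e-9)
  expect_lt(max(abs(pcc$values - t(pcc$values)), na.rm = TRUE), 1e-9)
})

test_that("every transform preserves symmetry", {
  m <- random_raw_cm(30, seed = 5, lambda = 40)
  b <- kr_balance(m)
  oe <- observed_expected(b)
  pcc <- pearson_correlation_matrix(oe)
  for (x in list(b, oe, pcc))
    expect_lt(max(abs(x$values - t(x$values)), na.rm = TRUE), 1e-9)
})
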