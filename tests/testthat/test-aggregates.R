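test_that("rescale_map is identity at size, block-averages down, preserves means", {
  set.seed(31)
  v <- matrix(rexp(90 * 90), 90, 90)
  expect_identical(rescale_map(v, 90), v)

  # 180 -> 90: each output cell is the mean of its 2x2 source block
  w <- matrix(rexp(180 * 180), 180, 180)
  out <- rescale_map(w, 90)
  ref <- matrix(0, 90, 90)
  for (i in 1:90) for (j in 1:90)
    ref[i, j] <- mean(w[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(out, ref, tolerance = 1e-12)
  # exact mean preservation under block-averaging
  expect_equal(mean(out), mean(w), tolerance = 1e-12)

  # fractional downsampling preserves the mean of block-constant input
  bc <- matrix(3.5, 120, 120)
  expect_equal(rescale_map(bc, 90), matrix(3.5, 90, 90), tolerance = 1e-12)

  # upsampling a constant map stays constant
  expect_equal(rescale_map(matrix(2, 30, 30), 90), matrix(2, 90, 90),
               tolerance = 1e-12)
})

test_that("tad_aggregate extracts, rescales and averages domains", {
  n <- 200
  bs <- 40000
  # one TAD of exactly 30 bins: 3L = 90 source bins, rescale is identity
  set.seed(7)
  m <- random_kind_cm(n, seed = 7, kind = "oe")
  a <- 61; len <- 30
  tad <- bins_to_gr(m, a)                   # placeholder; build exact below
  tad <- gr0("chrT", (a - 1) * bs, (a + len - 1) * bs)
  agg <- tad_aggregate(m, tad)
  expect_equal(agg$values, m$values[(a - len):(a + 2 * len - 1),
                                    (a - len):(a + 2 * len - 1)],
               tolerance = 1e-12)

  # uniform O/E -> aggregate of ones for mixed TAD lengths
  u <- contact_matrix(matrix(1, n, n), "chrT", bs, kind = "oe")
  tads <- c(gr0("chrT", 40 * bs, 60 * bs), gr0("chrT", 100 * bs, 130 * bs))
  expect_equal(tad_aggregate(u, tads)$values, matrix(1, 90, 90),
               tolerance = 1e-12)

  # degenerate / off-matrix domains are skipped
  small <- gr0("chrT", 50 * bs, 52 * bs)       # 2 bins < 3
  edge <- gr0("chrT", 0, 30 * bs)              # window leaves matrix
  agg <- tad_aggregate(u, c(tads, small, edge))
  expect_equal(agg$n_used, 2L)
  expect_equal(agg$n_skipped, 2L)
  expect_error(tad_aggregate(u, small), "no usable")
})

test_that("tad_strength implements the slice-sum ratio", {
  expect_equal(tad_strength(matrix(1, 90, 90)), 1)

  v <- matrix(1, 90, 90)
  v[31:60, 31:60] <- 2
  expect_equal(tad_strength(v), 2)

  set.seed(13)
  r <- matrix(rexp(90 * 90), 90, 90)
  expect_equal(tad_strength(r), tad_strength_oracle(r), tolerance = 1e-12)

  expect_error(tad_strength(matrix(0, 90, 90)), "zero")
  expect_error(tad_strength(matrix(1, 50, 50)), "90 x 90")
})

test_that("loop_aggregate averages anchor-pair windows", {
  n <- 300
  bs <- 10000
  u <- contact_matrix(matrix(1, n, n), "chrT", bs, kind = "oe")
  loops <- data.frame(chrom1 = "chrT", start1 = 99 * bs, end1 = 100 * bs,
                      chrom2 = "chrT", start2 = 199 * bs, end2 = 200 * bs)
  agg <- loop_aggregate(u, loops)
  expect_equal(dim(agg$values), c(31L, 31L))
  expect_equal(agg$values, matrix(1, 31, 31))

  # single loop with a 3x3 patch of 4 at its base
  v <- matrix(1, n, n)
  v[99:101, 199:201] <- 4
  v[199:201, 99:101] <- 4
  m <- contact_matrix(v, "chrT", bs, kind = "oe")
  agg <- loop_aggregate(m, loops)
  expect_equal(agg$values[15:17, 15:17], matrix(4, 3, 3))
  expect_equal(agg$values[1, 1], 1)

  # two loops equal the elementwise mean of the two extracted submaps
  loops2 <- rbind(loops,
                  data.frame(chrom1 = "chrT", start1 = 59 * bs,
                             end1 = 60 * bs, chrom2 = "chrT",
                             start2 = 239 * bs, end2 = 240 * bs))
  agg2 <- loop_aggregate(m, loops2)
  s1 <- v[85:115, 185:215]
  s2 <- v[45:75, 225:255]
  expect_equal(agg2$values, (s1 + s2) / 2, tolerance = 1e-12)

  # off-matrix loop skipped; none usable errors
  edge <- data.frame(chrom1 = "chrT", start1 = 0, end1 = bs,
                     chrom2 = "chrT", start2 = 10 * bs, end2 = 11 * bs)
  expect_equal(loop_aggregate(m, rbind(loops, edge))$n_skipped, 1L)
  expect_error(loop_aggregate(m, edge), "no usable")
})

test_that("loop_strength divides the base square by offset controls", {
  n <- 300
  bs <- 10000
  u <- contact_matrix(matrix(1, n, n), "chrT", bs, kind = "oe")
  # anchors at bins 100 and 190 so both diagonal offsets stay on-matrix
  loops <- data.frame(chrom1 = "chrT", start1 = 99 * bs, end1 = 100 * bs,
                      chrom2 = "chrT", start2 = 189 * bs, end2 = 190 * bs)
  expect_equal(loop_strength(u, loops), 1)

  v <- matrix(1, n, n)
  v[99:101, 189:191] <- 4
  v[189:191, 99:101] <- 4
  m <- contact_matrix(v, "chrT", bs, kind = "oe")
  expect_equal(loop_strength(m, loops), 4)

  # random map, 5 loops vs the per-loop oracle
  r <- random_kind_cm(n, seed = 17, kind = "oe", bin_size = bs)
  set.seed(5)
  a <- sample(30:120, 5)
  b <- a + sample(40:90, 5)
  loops5 <- data.frame(chrom1 = "chrT", start1 = (a - 1) * bs, end1 = a * bs,
                       chrom2 = "chrT", start2 = (b - 1) * bs, end2 = b * bs)
  expect_equal(loop_strength(r, loops5),
               loop_strength_oracle(r$values, cbind(a, b)),
               tolerance = 1e-12)

  # monotone in planted loop enrichment
  strengths <- vapply(c(1, 2, 4), function(en) {
    spec <- simulation_spec(n_bins = 300, bin_size = bs, chrom = "chrT",
                            loops = data.frame(anchor_a = c(80, 150),
                                               anchor_b = c(140, 230),
                                               enrichment = en),
                            depth = 3e6, seed = 41)
    sim <- simulate_hic(spec)
    oe <- observed_expected(kr_balance(sim$matrix))
    loopdf <- data.frame(chrom1 = "chrT",
                         start1 = (c(80, 150) - 1) * bs, end1 = c(80, 150) * bs,
                         chrom2 = "chrT",
                         start2 = (c(140, 230) - 1) * bs,
                         end2 = c(140, 230) * bs)
    loop_strength(oe, loopdf)
  }, numeric(1))
  expect_true(all(diff(strengths) > 0))
  expect_gt(strengths[3], strengths[1])
})
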