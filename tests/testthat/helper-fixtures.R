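# In-code fixtures shared across test files.

# random symmetric raw count matrix (Poisson around a decay curve)
random_raw_cm <- function(n, seed, lambda = 30, bin_size = 40000,
                          chrom = "chrT") {
  set.seed(seed)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- lambda / (d + 1)
  v <- matrix(0, n, n)
  ut <- upper.tri(v, diag = TRUE)
  v[ut] <- rpois(sum(ut), mu[ut])
  v <- v + t(v)
  diag(v) <- diag(v) / 2
  contact_matrix(v, chrom, bin_size)
}

# random symmetric positive matrix wrapped as a given kind
random_kind_cm <- function(n, seed, kind = "oe", bin_size = 40000,
                           chrom = "chrT", shift = 0.2) {
  set.seed(seed)
  v <- matrix(rexp(n * n) + shift, n, n)
  v <- (v + t(v)) / 2
  if (kind == "pcc") {
    v <- stats::cov2cor(crossprod(matrix(rnorm(2 * n * n), 2 * n, n)))
    v <- (v + t(v)) / 2
  }
  contact_matrix(v, chrom, bin_size, kind = kind)
}

# GRanges from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, strand = "*", name = ".") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand, name = name)
}

# bin index set -> GRanges on a matrix frame
bins_to_gr <- function(m, bins) {
  starts <- m$start_bp + (bins - 1) * m$bin_size
  gr0(m$chrom, starts, starts + m$bin_size)
}
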