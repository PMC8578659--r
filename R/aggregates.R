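#' Resample a square map to a fixed pixel size
#'
#' Downsampling (source larger than target) is exact block-averaging with
#' fractional edge weights; upsampling is bilinear interpolation on bin
#' centers (edge-clamped). Undefined (`NA`) source cells are excluded from
#' the averages; an output cell with no defined support is `NA`.
#' Block-averaging preserves the mean of block-constant inputs exactly.
#'
#' @param m square numeric matrix.
#' @param target output side length (default 90).
#' @return `target` x `target` numeric matrix.
#' @export
rescale_map <- function(m, target = 90) {
  n <- nrow(m)
  stopifnot(n == ncol(m))
  if (n == target) return(m)
  W <- if (n > target) overlap_weights(n, target) else bilinear_weights(n, target)
  def <- !is.na(m)
  m0 <- m
  m0[!def] <- 0
  num <- W %*% m0 %*% t(W)
  den <- W %*% (def + 0) %*% t(W)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# target x n row-stochastic matrix of interval-overlap weights
overlap_weights <- function(n, target) {
  W <- matrix(0, target, n)
  step <- n / target
  for (k in seq_len(target)) {
    lo <- (k - 1) * step
    hi <- k * step
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[k, j] <- ov
    }
    W[k, ] <- W[k, ] / sum(W[k, ])
  }
  W
}

# target x n bilinear weights on bin centers, clamped at the edges
bilinear_weights <- function(n, target) {
  W <- matrix(0, target, n)
  step <- n / target
  for (k in seq_len(target)) {
    x <- (k - 0.5) * step          # target-center position in source coords
    p <- x - 0.5                   # fractional source index (0-based centers)
    j <- floor(p)
    frac <- p - j
    j0 <- min(max(j, 0), n - 1)
    j1 <- min(max(j + 1, 0), n - 1)
    if (j < 0) { j0 <- j1 <- 0; frac <- 0 }
    if (j + 1 > n - 1) { j0 <- j1 <- n - 1; frac <- 0 }
    W[k, j0 + 1] <- W[k, j0 + 1] + (1 - frac)
    W[k, j1 + 1] <- W[k, j1 + 1] + frac
  }
  W
}

# TAD intervals -> bin coordinates (start bin, end bin inclusive), rounded
tad_bin_coords <- function(m, tads) {
  chroms <- unique(as.character(GenomicRanges::seqnames(tads)))
  if (length(chroms) && !all(chroms == m$chrom))
    stop("TAD chromosome(s) do not match matrix chromosome '", m$chrom, "'")
  s0 <- GenomicRanges::start(tads) - 1
  e0 <- GenomicRanges::end(tads)
  a <- round((s0 - m$start_bp) / m$bin_size) + 1
  b <- round((e0 - m$start_bp) / m$bin_size)
  cbind(a, b)
}

#' Rescaled aggregate TAD map
#'
#' For each domain of length L the 3L-wide submap from `start - L` to
#' `end + L` is extracted and resampled to a 90 x 90 pixel map
#' ([rescale_map()]); maps are then averaged cellwise over domains.
#' In the result, pixels 30-60 (0-based) on each axis span the TAD body.
#'
#' @param oe an O/E [contact_matrix()] (40 kb bins by convention).
#' @param tads `GRanges` of domains.
#' @param target output pixel size (default 90).
#' @return an `AggregateMap` of kind `"tad"`. Domains shorter than 3 bins
#'   or whose 3L window leaves the matrix are skipped and counted.
#' @export
tad_aggregate <- function(oe, tads, target = 90) {
  stopifnot(inherits(oe, "ContactMatrix"))
  if (oe$kind != "oe") stop("tad_aggregate expects an O/E matrix")
  bc <- tad_bin_coords(oe, tads)
  v <- oe$values
  nb <- nrow(v)
  acc <- matrix(0, target, target)
  cnt <- matrix(0L, target, target)
  used <- 0L; skipped <- 0L
  for (k in seq_len(nrow(bc))) {
    a <- bc[k, 1]; b <- bc[k, 2]
    len <- b - a + 1
    w0 <- a - len
    w1 <- b + len
    if (len < 3 || w0 < 1 || w1 > nb) { skipped <- skipped + 1L; next }
    sub <- rescale_map(v[w0:w1, w0:w1, drop = FALSE], target)
    def <- !is.na(sub)
    sub[!def] <- 0
    acc <- acc + sub
    cnt <- cnt + def
    used <- used + 1L
  }
  if (used == 0L) stop("no usable TADs (", skipped, " skipped)")
  vals <- acc / cnt
  vals[cnt == 0L] <- NA_real_
  structure(list(values = vals, n_elements = cnt, kind = "tad",
                 n_used = used, n_skipped = skipped),
            class = "AggregateMap")
}

#' TAD strength of a 90 x 90 aggregate map
#'
#' Ratio of within-TAD to between-TAD intensity: the sum of the central
#' square (rows/columns 30-59, 0-based) divided by half the sum of the two
#' flanking blocks `[0:30, 30:60]` and `[30:60, 60:90]` (0-based,
#' half-open).
#'
#' @param a a `tad_aggregate()` map (or a bare 90 x 90 matrix).
#' @return the strength ratio (a single number).
#' @export
tad_strength <- function(a) {
  v <- if (inherits(a, "AggregateMap")) a$values else a
  if (nrow(v) != 90 || ncol(v) != 90)
    stop("tad_strength expects a 90 x 90 map")
  within <- sum(v[31:60, 31:60], na.rm = TRUE)
  between <- (sum(v[1:30, 31:60], na.rm = TRUE) +
              sum(v[31:60, 61:90], na.rm = TRUE)) / 2
  if (between == 0) stop("between-TAD intensity is zero; strength undefined")
  within / between
}

# loop table (data.frame chrom1,start1,end1,chrom2,start2,end2) -> anchor bins
loop_anchor_bins <- function(m, loops) {
  stopifnot(is.data.frame(loops))
  bad <- c(as.character(loops$chrom1), as.character(loops$chrom2))
  if (!all(bad == m$chrom))
    stop("loop chromosome(s) do not match matrix chromosome '", m$chrom, "'")
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  ba <- floor((mid1 - m$start_bp) / m$bin_size) + 1
  bb <- floor((mid2 - m$start_bp) / m$bin_size) + 1
  swap <- ba > bb
  tmp <- ba[swap]; ba[swap] <- bb[swap]; bb[swap] <- tmp
  cbind(ba, bb)
}

#' Aggregate loop (pileup) map
#'
#' Averages O/E submaps in a `window_bp` window (default 310 kb, i.e.
#' 31 x 31 bins at 10 kb) centered on the bin pair containing the two loop
#' anchors. Loops whose window leaves the matrix are skipped and counted.
#'
#' @param oe10 an O/E [contact_matrix()] (10 kb bins by convention).
#' @param loops loop table as returned by [read_loops()]: data.frame with
#'   columns `chrom1, start1, end1, chrom2, start2, end2` (0-based,
#'   half-open anchors).
#' @param window_bp window span in bp (default 310000).
#' @return an `AggregateMap` of kind `"loop"`.
#' @export
loop_aggregate <- function(oe10, loops, window_bp = 310000) {
  stopifnot(inherits(oe10, "ContactMatrix"))
  if (oe10$kind != "oe") stop("loop_aggregate expects an O/E matrix")
  ab <- loop_anchor_bins(oe10, loops)
  half <- (round(window_bp / oe10$bin_size) - 1) %/% 2
  size <- 2L * half + 1L
  v <- oe10$values
  nb <- nrow(v)
  acc <- matrix(0, size, size)
  cnt <- matrix(0L, size, size)
  used <- 0L; skipped <- 0L
  for (k in seq_len(nrow(ab))) {
    ba <- ab[k, 1]; bb <- ab[k, 2]
    if (ba - half < 1 || bb + half > nb || ba + half > nb || bb - half < 1) {
      skipped <- skipped + 1L; next
    }
    sub <- v[(ba - half):(ba + half), (bb - half):(bb + half), drop = FALSE]
    def <- !is.na(sub)
    sub[!def] <- 0
    acc <- acc + sub
    cnt <- cnt + def
    used <- used + 1L
  }
  if (used == 0L) stop("no usable loops (", skipped, " skipped)")
  vals <- acc / cnt
  vals[cnt == 0L] <- NA_real_
  structure(list(values = vals, n_elements = cnt, kind = "loop",
                 n_used = used, n_skipped = skipped),
            class = "AggregateMap")
}

#' Loop strength against offset controls
#'
#' Per loop with anchors (a, b), the numerator is the mean O/E over the
#' square of `square_bins` x `square_bins` bins centered at the loop base
#' (3 x 3 bins, ~31 kb at 10 kb resolution); the denominator is the mean
#' over the same-size squares at the two positions offset diagonally by the
#' loop length L = b - a (i.e. (a-L, b-L) and (a+L, b+L)), using whichever
#' offsets lie on the matrix. The headline strength is the mean over loops
#' of numerator/denominator.
#'
#' @inheritParams loop_aggregate
#' @param square_bins scoring square side in bins (default 3).
#' @param detail return per-loop ratios and per-direction denominators as
#'   well (default `FALSE`).
#' @return the mean strength (or, with `detail = TRUE`, a list with
#'   `strength`, `per_loop`, `n_used`, `n_skipped`).
#' @export
loop_strength <- function(oe10, loops, square_bins = 3, detail = FALSE) {
  stopifnot(inherits(oe10, "ContactMatrix"))
  if (oe10$kind != "oe") stop("loop_strength expects an O/E matrix")
  ab <- loop_anchor_bins(oe10, loops)
  v <- oe10$values
  nb <- nrow(v)
  h <- (square_bins - 1) %/% 2
  sq_mean <- function(i, j) {
    if (i - h < 1 || j + h > nb || i + h > nb || j - h < 1) return(NA_real_)
    mean(v[(i - h):(i + h), (j - h):(j + h)], na.rm = TRUE)
  }
  ratios <- rep(NA_real_, nrow(ab))
  lower <- upper <- rep(NA_real_, nrow(ab))
  for (k in seq_len(nrow(ab))) {
    a <- ab[k, 1]; b <- ab[k, 2]
    L <- b - a
    num <- sq_mean(a, b)
    lower[k] <- sq_mean(a - L, b - L)
    upper[k] <- sq_mean(a + L, b + L)
    den <- mean(c(lower[k], upper[k]), na.rm = TRUE)
    if (is.na(num) || is.nan(den) || is.na(den) || den == 0) next
    ratios[k] <- num / den
  }
  ok <- !is.na(ratios)
  if (!any(ok)) stop("no loop with an on-matrix offset control")
  strength <- mean(ratios[ok])
  if (!detail) return(strength)
  list(strength = strength,
       per_loop = data.frame(anchor_a = ab[, 1], anchor_b = ab[, 2],
                             ratio = ratios, offset_lower = lower,
                             offset_upper = upper),
       n_used = sum(ok), n_skipped = sum(!ok))
}
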