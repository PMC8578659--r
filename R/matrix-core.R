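#' Downsample a raw contact matrix to a fixed read-pair total
#'
#' Equalizes sequencing depth across conditions before comparison by drawing
#' `target_total` read pairs without replacement from the multiset of
#' observed pairs (multivariate hypergeometric). The upper triangle
#' (including the diagonal) is sampled and mirrored, so the returned
#' upper-triangle total is exactly `target_total`.
#'
#' @param m a raw [contact_matrix()].
#' @param target_total number of read pairs to keep; must not exceed the
#'   current upper-triangle total.
#' @param seed integer seed (mandatory: sampling is stochastic).
#' @return a raw `ContactMatrix` with the same frame and mask.
#' @export
downsample_counts <- function(m, target_total, seed) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (m$kind != "raw") stop("downsampling requires a raw count matrix")
  v <- m$values
  ut <- upper.tri(v, diag = TRUE)
  counts <- v[ut]
  total <- sum(counts)
  if (target_total > total)
    stop("insufficient depth: target_total (", target_total,
         ") exceeds available pairs (", total, ")")
  if (target_total == total) return(m)
  set.seed(as.integer(seed))
  new_counts <- numeric(length(counts))
  take <- target_total       # pairs still to draw
  pool <- total              # pairs not yet partitioned
  for (k in which(counts > 0)) {
    if (take == 0) break
    ck <- counts[k]
    # conditional draw for this cell given what remains elsewhere
    x <- stats::rhyper(1, m = ck, n = pool - ck, k = take)
    new_counts[k] <- x
    take <- take - x
    pool <- pool - ck
  }
  out <- matrix(0, nrow(v), ncol(v))
  out[ut] <- new_counts
  out <- out + t(out)
  diag(out) <- diag(out) / 2
  contact_matrix(out, m$chrom, m$bin_size, m$start_bp, "raw", m$mask)
}

#' Balance a raw contact matrix (Knight-Ruiz style scaling)
#'
#' Finds per-bin weights `x` such that `diag(x) %*% M %*% diag(x)` has equal
#' row sums (normalized to 1) on unmasked bins, correcting per-bin coverage
#' bias. Bins with a zero raw marginal are masked before balancing. The
#' fixed point is the same as Knight-Ruiz / Sinkhorn balancing; the
#' iteration used here is the symmetric scaling `x <- x / sqrt(rowsum)`.
#'
#' @param m a raw [contact_matrix()].
#' @param tol convergence tolerance on the coefficient of variation of the
#'   unmasked row sums. Default `1e-6`.
#' @param max_iter maximum iterations. Default 3000.
#' @return a `ContactMatrix` of kind `"balanced"` with masked rows/columns
#'   set to `NA`; the balancing weights are in field `weights` (`NA` at
#'   masked bins).
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 3000) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (m$kind != "raw") stop("kr_balance expects a raw count matrix")
  v <- m$values
  nb <- nrow(v)
  marg <- rowSums(v, na.rm = TRUE)
  mask <- m$mask | marg == 0
  keep <- which(!mask)
  if (length(keep) == 0) stop("matrix is fully zero; nothing to balance")
  A <- v[keep, keep, drop = FALSE]
  x <- rep(1, length(keep))
  cv <- Inf
  for (it in seq_len(max_iter)) {
    r <- x * as.vector(A %*% x)          # row sums of diag(x) A diag(x)
    mu <- mean(r)
    cv <- stats::sd(r) / mu
    if (is.na(cv)) cv <- 0               # single unmasked bin
    if (cv < tol) break
    x <- x / sqrt(r / mu)
  }
  if (cv >= tol)
    stop("kr_balance did not converge after ", max_iter,
         " iterations (row-sum CV = ", format(cv), ")")
  r <- x * as.vector(A %*% x)
  x <- x / sqrt(mean(r))                 # unmasked row sums -> 1
  B <- (x %o% x) * A
  B <- (B + t(B)) / 2                    # kill rounding asymmetry
  out <- matrix(NA_real_, nb, nb)
  out[keep, keep] <- B
  w <- rep(NA_real_, nb)
  w[keep] <- x
  res <- contact_matrix(out, m$chrom, m$bin_size, m$start_bp, "balanced", mask)
  res$weights <- w
  res
}

#' Observed/expected transform
#'
#' Divides each entry by the expected contact frequency at its genomic
#' distance, where expected(d) is the arithmetic mean of defined entries on
#' diagonal d of the same chromosome. Diagonals with no defined entries, or
#' expected value 0, become `NA`. Over defined entries, each output diagonal
#' has mean exactly 1.
#'
#' @param m a balanced (or raw) [contact_matrix()].
#' @return a `ContactMatrix` of kind `"oe"`.
#' @export
observed_expected <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (!m$kind %in% c("balanced", "raw"))
    stop("observed_expected expects a balanced (or raw) matrix")
  v <- m$values
  nb <- nrow(v)
  out <- matrix(NA_real_, nb, nb)
  for (d in 0:(nb - 1)) {
    i <- seq_len(nb - d)
    idx <- cbind(i, i + d)
    vals <- v[idx]
    e <- mean(vals, na.rm = TRUE)
    if (is.nan(e) || is.na(e) || e == 0) next   # empty or zero-expected diagonal
    out[idx] <- vals / e
    out[idx[, 2:1, drop = FALSE]] <- vals / e
  }
  out[m$mask, ] <- NA_real_
  out[, m$mask] <- NA_real_
  contact_matrix(out, m$chrom, m$bin_size, m$start_bp, "oe", m$mask)
}

# Pairwise-complete Pearson correlation between the rows of v, computed
# with matrix products (equivalent to cor(..., use =
# "pairwise.complete.obs") but O(n^3) overall instead of per-pair).
pairwise_cor <- function(v) {
  D <- (!is.na(v)) + 0
  X <- v
  X[is.na(X)] <- 0
  N <- tcrossprod(D)
  S <- tcrossprod(X)
  SX <- tcrossprod(X, D)        # SX[i,j] = sum of row i over shared support
  Q <- tcrossprod(X * X, D)
  mi <- SX / N
  cv <- S / N - mi * t(mi)
  vi <- Q / N - mi^2
  r <- cv / sqrt(vi * t(vi))
  r[N < 2 | vi <= 1e-15 | t(vi) <= 1e-15] <- NA_real_
  r
}

#' Pearson-correlation transform of an O/E matrix
#'
#' Correlates every pair of O/E row vectors over their mutually defined
#' positions. Rows with zero variance (or masked bins) give `NA`; the
#' diagonal is 1 for defined bins; entries are clamped to `[-1, 1]`.
#'
#' @param m an O/E [contact_matrix()].
#' @return a `ContactMatrix` of kind `"pcc"`.
#' @export
pearson_correlation_matrix <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (m$kind != "oe") stop("pearson_correlation_matrix expects an O/E matrix")
  v <- m$values
  cc <- if (anyNA(v)) pairwise_cor(v) else suppressWarnings(stats::cor(v))
  cc[m$mask, ] <- NA_real_
  cc[, m$mask] <- NA_real_
  cc <- pmin(pmax(cc, -1), 1)
  defined <- !m$mask & apply(v, 1, function(r) any(!is.na(r)))
  # zero-variance rows: cor() already yields NA; fix the diagonal for the rest
  dg <- diag(cc)
  dg[defined & !is.na(dg)] <- 1
  diag(cc) <- dg
  cc <- (cc + t(cc)) / 2
  contact_matrix(cc, m$chrom, m$bin_size, m$start_bp, "pcc", m$mask)
}
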