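# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# plain alternating row/column Sinkhorn normalization, run to tight
# tolerance; returns the balanced matrix with row sums 1
sinkhorn_oracle <- function(A, tol = 1e-12, max_iter = 100000) {
  for (it in seq_len(max_iter)) {
    A <- A / rowSums(A)
    A <- t(t(A) / colSums(A))
    if (max(abs(rowSums(A) - 1)) < tol && max(abs(colSums(A) - 1)) < tol)
      return(A)
  }
  stop("sinkhorn oracle did not converge")
}

# per-diagonal mean division, written as explicit loops
oe_oracle <- function(v) {
  n <- nrow(v)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- abs(i - j)
    vals <- c()
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (b - a == d) vals <- c(vals, v[a, b])
    }
    e <- mean(vals, na.rm = TRUE)
    if (!is.nan(e) && !is.na(e) && e != 0 && !is.na(v[i, j]))
      out[i, j] <- v[i, j] / e
  }
  out
}

# textbook pairwise Pearson over mutually defined positions
pcc_oracle <- function(v) {
  n <- nrow(v)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(v[i, ]) & !is.na(v[j, ])
    if (sum(ok) < 2) next
    x <- v[i, ok]; y <- v[j, ok]
    sx <- sqrt(mean(x^2) - mean(x)^2)
    sy <- sqrt(mean(y^2) - mean(y)^2)
    if (sx <= 1e-8 || sy <= 1e-8) next
    out[i, j] <- (mean(x * y) - mean(x) * mean(y)) / (sx * sy)
  }
  out
}

# leading eigenvector of t(Cc) %*% Cc by power iteration (PC1 up to sign)
power_iteration_oracle <- function(C, iters = 5000) {
  Cc <- sweep(C, 2, colMeans(C))
  M <- t(Cc) %*% Cc
  x <- rep(1, ncol(M)) + seq_len(ncol(M)) / ncol(M)
  for (i in seq_len(iters)) {
    x <- M %*% x
    x <- x / sqrt(sum(x^2))
  }
  as.vector(x)
}

# naive O(n * w^2) insulation double loop
insulation_oracle <- function(v, w = 5) {
  n <- nrow(v)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    acc <- c()
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w))
      acc <- c(acc, v[a, b])
    if (any(!is.na(acc))) raw[i] <- mean(acc, na.rm = TRUE)
  }
  norm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(raw[i])) next
    idx <- setdiff(max(1, i - 25):min(n, i + 25), i)
    loc <- mean(raw[idx], na.rm = TRUE)
    if (!is.na(loc) && loc > 0 && raw[i] > 0) norm[i] <- log2(raw[i] / loc)
  }
  list(raw = raw, normalized = norm)
}

# saddle cell means by enumeration over ordered entry pairs
saddle_oracle <- function(v, groups, k = 5) {
  out <- matrix(NA_real_, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    acc <- c()
    for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
      if (!is.na(groups[i]) && !is.na(groups[j]) &&
          groups[i] == a && groups[j] == b && !is.na(v[i, j]))
        acc <- c(acc, v[i, j])
    }
    if (length(acc)) out[a, b] <- mean(acc)
  }
  out
}

# explicit slice sums for the 90x90 TAD strength
tad_strength_oracle <- function(v) {
  within <- 0
  flank1 <- 0
  flank2 <- 0
  for (i in 1:90) for (j in 1:90) {
    if (i >= 31 && i <= 60 && j >= 31 && j <= 60) within <- within + v[i, j]
    if (i >= 1 && i <= 30 && j >= 31 && j <= 60) flank1 <- flank1 + v[i, j]
    if (i >= 31 && i <= 60 && j >= 61 && j <= 90) flank2 <- flank2 + v[i, j]
  }
  within / ((flank1 + flank2) / 2)
}

# per-loop ratio oracle with explicit square means
loop_strength_oracle <- function(v, anchors, h = 1) {
  n <- nrow(v)
  sq <- function(i, j) {
    if (i - h < 1 || i + h > n || j - h < 1 || j + h > n) return(NA_real_)
    acc <- c()
    for (a in (i - h):(i + h)) for (b in (j - h):(j + h))
      acc <- c(acc, v[a, b])
    mean(acc, na.rm = TRUE)
  }
  ratios <- c()
  for (k in seq_len(nrow(anchors))) {
    a <- anchors[k, 1]; b <- anchors[k, 2]; L <- b - a
    num <- sq(a, b)
    den <- mean(c(sq(a - L, b - L), sq(a + L, b + L)), na.rm = TRUE)
    if (!is.na(num) && !is.nan(den) && !is.na(den) && den != 0)
      ratios <- c(ratios, num / den)
  }
  mean(ratios)
}

# mean-PCC difference by explicit pair enumeration
pcc_diff_oracle <- function(va, vb, xb, yb) {
  acc_a <- c(); acc_b <- c()
  for (i in xb) for (j in yb) {
    if (i == j) next
    if (is.na(va[i, j]) || is.na(vb[i, j])) next
    acc_a <- c(acc_a, va[i, j]); acc_b <- c(acc_b, vb[i, j])
  }
  mean(acc_a) - mean(acc_b)
}
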