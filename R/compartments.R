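#' Compartment eigenvector (PC1) of a correlation matrix
#'
#' Leading principal-component loading of the Hi-C Pearson-correlation
#' matrix: the unit-norm first eigenvector of the column-centered PCC
#' matrix. Positive and negative signs partition bins into the two
#' compartments; the global sign is arbitrary until [orient_by_gc()].
#'
#' @param pcc a PCC [contact_matrix()] with at least 3 defined bins.
#' @return a [genome_track()] with one loading per bin (`NA` on masked /
#'   undefined bins).
#' @export
compute_pc1 <- function(pcc) {
  stopifnot(inherits(pcc, "ContactMatrix"))
  if (pcc$kind != "pcc") stop("compute_pc1 expects a PCC matrix")
  v <- pcc$values
  keep <- which(!pcc$mask & apply(v, 1, function(r) any(!is.na(r))))
  if (length(keep) < 3) stop("need at least 3 defined bins for PC1")
  C <- v[keep, keep, drop = FALSE]
  # rows with NA against defined bins (zero-variance rows) cannot enter PCA
  ok <- rowSums(is.na(C)) == 0
  keep <- keep[ok]
  C <- C[ok, ok, drop = FALSE]
  if (nrow(C) < 3) stop("need at least 3 defined bins for PC1")
  p <- stats::prcomp(C, center = TRUE, scale. = FALSE)
  if (p$sdev[1] < 1e-12)
    stop("correlation matrix has zero variance; PC1 undefined")
  out <- rep(NA_real_, n_bins(pcc))
  out[keep] <- p$rotation[, 1]
  genome_track(out, pcc$chrom, pcc$bin_size, pcc$start_bp)
}

#' Orient a compartment eigenvector by GC content
#'
#' By convention the A (active) compartment is GC-rich. The eigenvector
#' sign is flipped when the mean GC over negative-PC1 bins exceeds the mean
#' GC over positive-PC1 bins, so that positive PC1 = A afterwards.
#'
#' @param pc1 PC1 [genome_track()].
#' @param gc GC-fraction [genome_track()] on the same frame (values in
#'   `[0, 1]`).
#' @return the oriented `GenomeTrack`. If all defined entries share one
#'   sign the track is returned unchanged with a warning and attribute
#'   `one_sided = TRUE`.
#' @export
orient_by_gc <- function(pc1, gc) {
  if (length(pc1$values) != length(gc$values))
    stop("pc1 and gc tracks differ in length")
  v <- pc1$values
  pos <- which(!is.na(v) & v > 0)
  neg <- which(!is.na(v) & v < 0)
  if (length(pos) == 0 || length(neg) == 0) {
    warning("PC1 has a single sign; GC orientation not applicable")
    attr(pc1, "one_sided") <- TRUE
    return(pc1)
  }
  if (mean(gc$values[neg], na.rm = TRUE) > mean(gc$values[pos], na.rm = TRUE))
    pc1$values <- -v
  pc1
}

# Quantile-group assignment of defined bins by PC1, stable in bin order.
# Returns integer group 1..n_groups per bin (NA where undefined).
pc1_quantile_groups <- function(pc1, mask, n_groups = 5) {
  v <- pc1$values
  keep <- which(!is.na(v) & !mask)
  if (length(keep) < n_groups)
    stop("need at least ", n_groups, " defined bins for quantile assignment")
  ord <- order(v[keep])                      # stable: ties keep bin order
  g <- integer(length(keep))
  g[ord] <- floor((seq_along(ord) - 1) * n_groups / length(ord)) + 1L
  out <- rep(NA_integer_, length(v))
  out[keep] <- g
  out
}

#' Saddle map: average O/E by PC1 quantile pair
#'
#' Defined bins are split into five groups by PC1 percentile (minimum to
#' 20th percentile, 20th to 40th, ...). Cell (a, b) is the mean O/E over
#' all defined matrix entries whose bins fall in groups a and b. Corner
#' blocks of the resulting 5x5 map quantify compartmentalization.
#'
#' @param oe an O/E [contact_matrix()].
#' @param pc1 oriented PC1 [genome_track()] on the same frame.
#' @param n_groups number of quantile groups (default 5).
#' @return an object of class `SaddleMap`: list with `values` (5x5 means),
#'   `n_pairs` (contributing entry counts), `bin_edges` (PC1 cut points),
#'   `groups` (per-bin assignment) and `contributors` (per-cell O/E value
#'   lists, used by the bootstrap).
#' @export
saddle <- function(oe, pc1, n_groups = 5) {
  stopifnot(inherits(oe, "ContactMatrix"))
  if (oe$kind != "oe") stop("saddle expects an O/E matrix")
  grp <- pc1_quantile_groups(pc1, oe$mask, n_groups)
  v <- oe$values
  vals <- matrix(NA_real_, n_groups, n_groups)
  npairs <- matrix(0L, n_groups, n_groups)
  contributors <- vector("list", n_groups * n_groups)
  dim(contributors) <- c(n_groups, n_groups)
  for (a in seq_len(n_groups)) {
    for (b in a:n_groups) {
      ga <- which(!is.na(grp) & grp == a)
      gb <- which(!is.na(grp) & grp == b)
      x <- v[ga, gb, drop = FALSE]
      x <- x[!is.na(x)]
      contributors[[a, b]] <- x
      contributors[[b, a]] <- x
      npairs[a, b] <- npairs[b, a] <- length(x)
      if (length(x)) vals[a, b] <- vals[b, a] <- mean(x)
    }
  }
  edges <- stats::quantile(pc1$values[!is.na(grp)],
                           probs = seq(0, 1, length.out = n_groups + 1),
                           names = FALSE)
  structure(list(values = vals, n_pairs = npairs, bin_edges = edges,
                 groups = grp, contributors = contributors),
            class = "SaddleMap")
}

#' @export
print.SaddleMap <- function(x, ...) {
  cat("<SaddleMap>", nrow(x$values), "x", ncol(x$values), "mean O/E\n")
  print(round(x$values, 3))
  invisible(x)
}

saddle_blocks <- function(vals) {
  k <- nrow(vals)
  stopifnot(k == 5)
  AA <- sum(vals[1:3, 1:3])
  BB <- sum(vals[3:5, 3:5])
  AB <- (sum(vals[1:3, 3:5]) + sum(vals[3:5, 1:3])) / 2
  list(AA = AA, BB = BB, AB = AB)
}

#' Compartment strength from a saddle map
#'
#' Strength is `ln((AA * BB) / AB^2)` where AA is the sum of saddle rows
#' 1-3 x columns 1-3, BB rows 3-5 x columns 3-5 (the middle quantile is
#' shared, as defined), and AB the mean of the two symmetric off-blocks
#' (rows 1-3 x columns 3-5 and rows 3-5 x columns 1-3). The optional
#' bootstrap resamples, for each saddle cell, its contributing O/E values
#' with replacement (same size) and recomputes the strength.
#'
#' @param s a [saddle()] map.
#' @param n_boot bootstrap replicates (0 = none; the field convention is
#'   100).
#' @param seed integer seed for the bootstrap.
#' @return an object of class `CompartmentStrength`: list with `strength`,
#'   `AA`, `BB`, `AB` and (when `n_boot > 0`) `bootstrap`, a numeric vector
#'   of resampled strengths.
#' @export
compartment_strength <- function(s, n_boot = 0, seed = 1) {
  stopifnot(inherits(s, "SaddleMap"))
  if (any(is.na(s$values)))
    stop("saddle map has empty cells; strength undefined")
  bl <- saddle_blocks(s$values)
  if (bl$AB == 0) stop("degenerate saddle: AB block sums to 0")
  strength <- log((bl$AA * bl$BB) / bl$AB^2)
  boot <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    k <- nrow(s$values)
    boot <- vapply(seq_len(n_boot), function(b) {
      vals <- matrix(NA_real_, k, k)
      for (a in seq_len(k)) for (j in a:k) {
        x <- s$contributors[[a, j]]
        xs <- x[sample.int(length(x), length(x), replace = TRUE)]
        vals[a, j] <- vals[j, a] <- mean(xs)
      }
      blb <- saddle_blocks(vals)
      log((blb$AA * blb$BB) / blb$AB^2)
    }, numeric(1))
  }
  structure(list(strength = strength, AA = bl$AA, BB = bl$BB, AB = bl$AB,
                 bootstrap = boot),
            class = "CompartmentStrength")
}

#' @export
print.CompartmentStrength <- function(x, ...) {
  cat(sprintf("<CompartmentStrength> ln(AA*BB/AB^2) = %.4f", x$strength))
  if (!is.null(x$bootstrap))
    cat(sprintf("  (bootstrap sd %.4f, n = %d)",
                stats::sd(x$bootstrap), length(x$bootstrap)))
  cat("\n")
  invisible(x)
}
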