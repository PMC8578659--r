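# Contact enrichment of genomic region sets vs. random-region nulls:
# the statistics used to compare contact density within a heterochromatin
# block (PNH) and between a focal locus and that block across conditions.

# unordered cross pairs between two disjoint (or equal) bin index sets;
# returns the matrix values at those pairs, NA dropped
pair_values <- function(m, bins_i, bins_j) {
  v <- m$values
  if (identical(bins_i, bins_j)) {
    if (length(bins_i) < 2) return(numeric(0))
    cmb <- utils::combn(bins_i, 2)
    vals <- v[cbind(cmb[1, ], cmb[2, ])]
  } else {
    g <- expand.grid(i = bins_i, j = bins_j)
    g <- g[g$i != g$j, , drop = FALSE]
    vals <- v[cbind(g$i, g$j)]
  }
  vals[!is.na(vals)]
}

#' Contact values within a region set
#'
#' All defined matrix entries (i, j), i < j, with both bins overlapping the
#' region set. The conventional summary is the mean; the full value list is
#' returned so it can feed the Mann-Whitney comparison against random
#' regions.
#'
#' @param m a [contact_matrix()] (O/E at 150 kb by convention, but any
#'   kind is accepted).
#' @param regions `GRanges` region set.
#' @return numeric vector of contact values.
#' @export
contacts_within <- function(m, regions) {
  bins <- region_bins(m, regions)
  if (length(bins) < 2)
    stop("fewer than 2 in-set bins; contacts_within undefined")
  pair_values(m, bins, bins)
}

#' Contact values between a focal locus and a region set
#'
#' All defined entries with one bin in the focal interval and one in the
#' region set, excluding pairs lying entirely within the focal interval.
#'
#' @param m a [contact_matrix()].
#' @param focal `GRanges` with the focal interval(s) (e.g. a 1.5 Mb window
#'   around a Dux-like locus).
#' @param regions `GRanges` region set.
#' @return numeric vector of contact values.
#' @export
contacts_between <- function(m, focal, regions) {
  fb <- region_bins(m, focal)
  rb <- setdiff(region_bins(m, regions), fb)
  if (length(fb) == 0 || length(rb) == 0)
    stop("no defined focal/region bin pairs")
  pair_values(m, fb, rb)
}

#' Random region sets matched to a template
#'
#' Draws `n_replicates` region sets preserving the number and length
#' multiset of the template intervals. Each interval is placed uniformly on
#' its own chromosome, non-overlapping within a replicate and avoiding
#' `exclude` regions (e.g. masked bins); deterministic given `seed`.
#'
#' @param template `GRanges` template region set.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_replicates number of replicates (default 10).
#' @param seed integer seed.
#' @param exclude optional `GRanges` that placements must not overlap.
#' @param max_retries placement retries per interval before erroring
#'   (default 1000).
#' @return list of `GRanges`, one per replicate.
#' @export
sample_random_regions <- function(template, chrom_sizes, n_replicates = 10,
                                  seed = 1, exclude = NULL,
                                  max_retries = 1000) {
  chroms <- as.character(GenomicRanges::seqnames(template))
  if (!all(chroms %in% names(chrom_sizes)))
    stop("chrom_sizes is missing chromosome(s): ",
         paste(setdiff(chroms, names(chrom_sizes)), collapse = ","))
  widths <- GenomicRanges::width(template)
  set.seed(as.integer(seed))
  lapply(seq_len(n_replicates), function(r) {
    placed_s <- numeric(0); placed_e <- numeric(0); placed_c <- character(0)
    for (k in order(widths, decreasing = TRUE)) {   # big intervals first
      len <- widths[k]; chr <- chroms[k]
      size <- chrom_sizes[[chr]]
      if (size < len)
        stop("chromosome ", chr, " shorter than interval of length ", len)
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        s0 <- floor(stats::runif(1, 0, size - len + 1))   # 0-based start
        e0 <- s0 + len
        same <- placed_c == chr
        if (any(same & placed_s < e0 & placed_e > s0)) next
        if (!is.null(exclude)) {
          cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(s0 + 1, e0))
          if (length(GenomicRanges::findOverlaps(cand, exclude)) > 0) next
        }
        placed_s <- c(placed_s, s0); placed_e <- c(placed_e, e0)
        placed_c <- c(placed_c, chr)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("failed to place an interval of length ", len, " on ", chr,
             " after ", max_retries, " retries")
    }
    gr <- GenomicRanges::GRanges(placed_c,
                                 IRanges::IRanges(placed_s + 1, placed_e))
    GenomicRanges::sort(gr)
  })
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum statistic with midrank ties. The two-sided p-value is exact
#' (null distribution of U) when `length(x) * length(y) <= 400` and there
#' are no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections. Reported U is the statistic for `x`.
#'
#' @param x,y nonempty numeric vectors.
#' @return list with `U` and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 * n2 <= 400) {
    pl <- stats::pwilcox(U, n1, n2)
    pu <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(pl, pu))
  } else {
    mu <- n1 * n2 / 2
    nt <- table(c(x, y))
    tie_term <- sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = max(p, .Machine$double.xmin))
}

#' Contact enrichment of a region set against random-region nulls
#'
#' Observed contact values ([contacts_within()], or [contacts_between()]
#' when `focal` is given) are compared with the values obtained on
#' `n_replicates` random region sets matched for number and length
#' ([sample_random_regions()]); each replicate gives a two-sided
#' Mann-Whitney U p-value and the replicate p-values are averaged
#' (the `N = 10, averaged p` convention). Masked bins are excluded from
#' both observed and null lists; random placements avoid masked bins.
#'
#' @inheritParams contacts_within
#' @param focal optional `GRanges` focal interval; when given, the
#'   statistic is focal-to-regions contact.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_replicates null replicates (default 10).
#' @param seed integer seed.
#' @return an `EnrichmentResult`: list with `observed_values`,
#'   `null_values` (per-replicate lists), `u_stats`, `p_values`, `p_mean`,
#'   `direction` (sign of observed mean minus pooled null mean),
#'   `n_replicates` and `seed`.
#' @export
enrichment_test <- function(m, regions, focal = NULL, chrom_sizes,
                            n_replicates = 10, seed = 1) {
  observed <- if (is.null(focal)) contacts_within(m, regions)
              else contacts_between(m, focal, regions)
  masked <- which(m$mask)
  exclude <- NULL
  if (length(masked)) {
    starts <- m$start_bp + (masked - 1) * m$bin_size
    exclude <- GenomicRanges::reduce(GenomicRanges::GRanges(
      m$chrom, IRanges::IRanges(starts + 1, starts + m$bin_size)))
  }
  nulls <- sample_random_regions(regions, chrom_sizes, n_replicates,
                                 seed = seed, exclude = exclude)
  null_values <- lapply(nulls, function(gr) {
    if (is.null(focal)) contacts_within(m, gr)
    else contacts_between(m, focal, gr)
  })
  tests <- lapply(null_values, function(nv) mann_whitney_u(observed, nv))
  p_values <- vapply(tests, `[[`, numeric(1), "p")
  structure(list(
    observed_values = observed,
    null_values = null_values,
    u_stats = vapply(tests, `[[`, numeric(1), "U"),
    p_values = p_values,
    p_mean = mean(p_values),
    direction = sign(mean(observed) - mean(unlist(null_values))),
    n_replicates = n_replicates,
    seed = seed),
    class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "<EnrichmentResult> observed mean %.4f vs null mean %.4f (%s), p_mean = %.3g (N = %d)\n",
    mean(x$observed_values), mean(unlist(x$null_values)),
    if (x$direction >= 0) "enriched" else "depleted",
    x$p_mean, x$n_replicates))
  invisible(x)
}

#' Difference of mean Pearson correlation between two conditions
#'
#' Mean PCC over bin pairs (one bin in `set_x`, one in `set_y`, excluding
#' identical bins) in condition `a` minus the same mean in condition `b`;
#' only pairs defined in both matrices contribute.
#'
#' @param pcc_a,pcc_b PCC [contact_matrix()] objects on the same frame.
#' @param set_x,set_y `GRanges` region sets.
#' @return the PCC difference (single number).
#' @export
pcc_difference <- function(pcc_a, pcc_b, set_x, set_y) {
  check_same_frame(pcc_a, pcc_b)
  xb <- intersect(region_bins(pcc_a, set_x), region_bins(pcc_b, set_x))
  yb <- intersect(region_bins(pcc_a, set_y), region_bins(pcc_b, set_y))
  g <- expand.grid(i = xb, j = yb)
  g <- g[g$i != g$j, , drop = FALSE]
  if (nrow(g) == 0) stop("no defined bin pairs between the two sets")
  va <- pcc_a$values[cbind(g$i, g$j)]
  vb <- pcc_b$values[cbind(g$i, g$j)]
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) stop("no pair defined in both matrices")
  mean(va[ok]) - mean(vb[ok])
}

#' log2 fold-change of contacts between a region set and gene sets
#'
#' For each gene set, `log2(mean_a / mean_b)` of the contact values between
#' `set_x` and the gene set in the two conditions. The two matrices should
#' be depth-matched first (see [downsample_counts()]); only pairs defined
#' in both matrices contribute.
#'
#' @param m_a,m_b [contact_matrix()] objects on the same frame (same kind).
#' @param set_x `GRanges` anchor region set.
#' @param gene_sets named list of `GRanges` gene sets.
#' @return data.frame with columns `set`, `n_pairs`, `mean_a`, `mean_b`,
#'   `log2fc` (`NA` when a mean is zero or no pair is defined).
#' @export
contacts_log2fc <- function(m_a, m_b, set_x, gene_sets) {
  check_same_frame(m_a, m_b)
  stopifnot(is.list(gene_sets), length(names(gene_sets)) == length(gene_sets))
  xb <- intersect(region_bins(m_a, set_x), region_bins(m_b, set_x))
  rows <- lapply(names(gene_sets), function(nm) {
    gb <- intersect(region_bins(m_a, gene_sets[[nm]]),
                    region_bins(m_b, gene_sets[[nm]]))
    gb <- setdiff(gb, xb)
    g <- expand.grid(i = xb, j = gb)
    va <- m_a$values[cbind(g$i, g$j)]
    vb <- m_b$values[cbind(g$i, g$j)]
    ok <- !is.na(va) & !is.na(vb)
    ma <- if (any(ok)) mean(va[ok]) else NA_real_
    mb <- if (any(ok)) mean(vb[ok]) else NA_real_
    lfc <- if (!any(ok) || is.na(mb) || mb == 0 || ma == 0) NA_real_
           else log2(ma / mb)
    data.frame(set = nm, n_pairs = sum(ok), mean_a = ma, mean_b = mb,
               log2fc = lfc)
  })
  do.call(rbind, rows)
}
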