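# Entropy-based stage-specificity scoring and K-means staging clusters
# for genes x developmental-stages expression tables (TPM).

#' Entropy-based stage-specificity score
#'
#' For a gene with stage profile `x`, let `p_s = x_s / sum(x)`. The score
#' is `1 - H(p) / log2(K)` with `H(p) = -sum(p_s log2 p_s)` (0 log 0 = 0)
#' and K the number of stages: 1 for a one-hot profile, 0 for a uniform
#' one. Genes with an all-zero profile get `NA`.
#'
#' @param e numeric genes x stages matrix of nonnegative abundances (TPM),
#'   with at least 2 stage columns.
#' @param log_transform compute the score on `log2(TPM + 1)` instead of
#'   raw TPM (default `FALSE`).
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
specificity_score <- function(e, log_transform = FALSE) {
  e <- as.matrix(e)
  if (ncol(e) < 2) stop("need at least 2 stages")
  if (any(e < 0, na.rm = TRUE)) stop("abundances must be nonnegative")
  if (log_transform) e <- log2(e + 1)
  tot <- rowSums(e)
  p <- e / tot
  plp <- p * log2(p)
  plp[p == 0] <- 0
  H <- -rowSums(plp)
  score <- 1 - H / log2(ncol(e))
  score[tot == 0] <- NA_real_
  score
}

#' K-means staging clusters of stage-specific genes
#'
#' Genes with specificity score above `threshold` are clustered on their
#' row-standardized `log2(TPM + 1)` stage profiles with K-means
#' (best of `nstart` random restarts). Clusters are relabeled C1..Ck by
#' the stage at which their centroid peaks, earliest first, so that C1 is
#' the earliest-stage cluster.
#'
#' @inheritParams specificity_score
#' @param scores per-gene scores from [specificity_score()].
#' @param threshold keep genes with `score > threshold` (default 0.2).
#' @param k number of clusters (default 4).
#' @param seed integer seed for the restarts.
#' @param nstart random restarts (default 50).
#' @return an object of class `StageClusters`: list with `assignments`
#'   (named factor with levels C1..Ck), `centroids` (k x stages, relabeled),
#'   `scores`, `threshold`, `k` and `genes` (the passing gene names).
#' @export
cluster_stage_genes <- function(e, scores, threshold = 0.2, k = 4,
                                seed = 1, nstart = 50) {
  e <- as.matrix(e)
  pass <- which(!is.na(scores) & scores > threshold)
  if (length(pass) < k)
    stop("only ", length(pass), " genes pass the threshold; need >= k = ", k)
  prof <- log2(e[pass, , drop = FALSE] + 1)
  prof <- t(apply(prof, 1, function(r) (r - mean(r)) / stats::sd(r)))
  set.seed(as.integer(seed))
  km <- stats::kmeans(prof, centers = k, nstart = nstart, iter.max = 100)
  peak <- apply(km$centers, 1, which.max)
  ord <- order(peak)                       # earliest-peaking centroid -> C1
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- factor(paste0("C", relabel[km$cluster]),
                   levels = paste0("C", seq_len(k)))
  names(labels) <- rownames(e)[pass]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("C", seq_len(k))
  structure(list(assignments = labels, centroids = centroids,
                 scores = scores, threshold = threshold, k = k,
                 genes = rownames(e)[pass]),
            class = "StageClusters")
}

#' @export
print.StageClusters <- function(x, ...) {
  cat(sprintf("<StageClusters> k = %d, %d genes above score %.2f\n",
              x$k, length(x$assignments), x$threshold))
  print(table(x$assignments))
  invisible(x)
}

#' Per-cluster expression-shift test
#'
#' For each gene, shift = `log2(TPM_treated + 1) - log2(TPM_control + 1)`.
#' Each cluster's shift distribution is compared with the shifts of all
#' genes by the two-sided Mann-Whitney U test ([mann_whitney_u()]).
#'
#' @param clusters a [cluster_stage_genes()] result.
#' @param expr_control,expr_treated genes x stages (or genes x samples)
#'   TPM matrices with matching rownames; per-gene shift is the mean over
#'   columns.
#' @return data.frame with columns `cluster`, `n_genes`, `mean_shift`,
#'   `median_shift`, `U`, `p` (a cluster with no measured genes gives an
#'   `NA` row).
#' @export
cluster_shift_test <- function(clusters, expr_control, expr_treated) {
  stopifnot(inherits(clusters, "StageClusters"))
  expr_control <- as.matrix(expr_control)
  expr_treated <- as.matrix(expr_treated)
  common <- intersect(rownames(expr_control), rownames(expr_treated))
  if (length(common) == 0) stop("no shared genes between the two tables")
  shift <- rowMeans(log2(expr_treated[common, , drop = FALSE] + 1) -
                    log2(expr_control[common, , drop = FALSE] + 1))
  rows <- lapply(levels(clusters$assignments), function(cl) {
    genes <- intersect(names(clusters$assignments)[clusters$assignments == cl],
                       common)
    if (length(genes) == 0)
      return(data.frame(cluster = cl, n_genes = 0L, mean_shift = NA_real_,
                        median_shift = NA_real_, U = NA_real_, p = NA_real_))
    mw <- mann_whitney_u(shift[genes], shift)
    data.frame(cluster = cl, n_genes = length(genes),
               mean_shift = mean(shift[genes]),
               median_shift = stats::median(shift[genes]),
               U = mw$U, p = mw$p)
  })
  do.call(rbind, rows)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for random
#' agreement. Used to check planted-cluster recovery.
#'
#' @param a,b equal-length label vectors.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
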