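# Ground-truth generators: a cis Hi-C map with power-law distance decay and
# planted compartments / TADs / loops / a high-contact heterochromatin block
# plus a focal locus, and a stage-patterned expression table with planted
# clusters. Every downstream statistic has a parameter-recovery test built
# on these, so nothing requires external data.

#' Specification of a synthetic cis Hi-C map
#'
#' The expected matrix is a product of factors on top of a power-law
#' distance decay `(|i - j| + 1)^-alpha`:
#' * compartments: same-label pairs x `sqrt(compartment_contrast)`,
#'   cross-label pairs x `1/sqrt(compartment_contrast)`, so the planted
#'   within/between O/E ratio equals `compartment_contrast` exactly;
#' * TADs: pairs inside the same domain x its contrast;
#' * loops: a 3 x 3 patch at each anchor pair x its enrichment;
#' * PNH block: pairs within the block x `pnh_contrast`;
#' * focal locus: pairs (focal bin, block bin) x `focal_contrast`.
#' The matrix is scaled so the expected upper-triangle total equals
#' `depth`, then Poisson counts are drawn on the upper triangle and
#' mirrored.
#'
#' @param n_bins number of bins (default 600).
#' @param bin_size bin width in bp (default 150000; a 90 Mb
#'   pseudo-chromosome at the defaults).
#' @param chrom chromosome name (default "chrS").
#' @param decay_exponent power-law decay exponent alpha (default 1).
#' @param compartment_block block length in bins of the alternating A/B
#'   pattern (default 20; ~3 Mb blocks at 150 kb).
#' @param compartment_labels optional explicit +1/-1 label vector
#'   (overrides `compartment_block`).
#' @param compartment_contrast within/between compartment O/E ratio
#'   (default 1 = no compartments).
#' @param tads optional data.frame `start_bin, end_bin, contrast`
#'   (1-based inclusive bins).
#' @param loops optional data.frame `anchor_a, anchor_b, enrichment`
#'   (1-based bins).
#' @param pnh_bins optional integer vector of block bins.
#' @param pnh_contrast within-block contact multiplier (default 1).
#' @param focal_bins optional integer vector of focal-locus bins.
#' @param focal_contrast focal-to-block contact multiplier (default 1).
#' @param depth expected total read pairs (upper triangle; default 2e6).
#' @param gc_base,gc_delta GC track: `gc_base` everywhere, plus
#'   `gc_delta` on A (+1) bins.
#' @param seed integer seed.
#' @return an object of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_bins = 600, bin_size = 150000, chrom = "chrS",
                            decay_exponent = 1, compartment_block = 20,
                            compartment_labels = NULL,
                            compartment_contrast = 1,
                            tads = NULL, loops = NULL,
                            pnh_bins = NULL, pnh_contrast = 1,
                            focal_bins = NULL, focal_contrast = 1,
                            depth = 2e6, gc_base = 0.41, gc_delta = 0.04,
                            seed = 1) {
  if (is.null(compartment_labels))
    compartment_labels <- rep_len(rep(c(1, -1), each = compartment_block),
                                  n_bins)
  stopifnot(length(compartment_labels) == n_bins,
            all(compartment_labels %in% c(-1, 1)))
  if (depth <= 0) stop("depth must be positive")
  if (compartment_contrast <= 0 || pnh_contrast <= 0 || focal_contrast <= 0)
    stop("all contrasts must be positive")
  check_bins <- function(b, what) {
    if (!is.null(b) && (any(b < 1) || any(b > n_bins)))
      stop(what, " outside the matrix (1..", n_bins, ")")
  }
  if (!is.null(tads)) {
    stopifnot(all(c("start_bin", "end_bin", "contrast") %in% names(tads)))
    check_bins(c(tads$start_bin, tads$end_bin), "TAD bins")
    if (any(tads$contrast <= 0)) stop("all contrasts must be positive")
  }
  if (!is.null(loops)) {
    stopifnot(all(c("anchor_a", "anchor_b", "enrichment") %in% names(loops)))
    check_bins(c(loops$anchor_a, loops$anchor_b), "loop anchors")
    if (any(loops$enrichment <= 0)) stop("all contrasts must be positive")
  }
  check_bins(pnh_bins, "PNH bins")
  check_bins(focal_bins, "focal bins")
  structure(list(
    n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
    chrom = chrom, decay_exponent = decay_exponent,
    compartment_labels = compartment_labels,
    compartment_contrast = compartment_contrast,
    tads = tads, loops = loops,
    pnh_bins = pnh_bins, pnh_contrast = pnh_contrast,
    focal_bins = focal_bins, focal_contrast = focal_contrast,
    depth = depth, gc_base = gc_base, gc_delta = gc_delta,
    seed = as.integer(seed)),
    class = "SimulationSpec")
}

# deterministic expected matrix for a spec (before Poisson sampling)
expected_matrix <- function(spec) {
  n <- spec$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- (d + 1)^(-spec$decay_exponent)
  lab <- spec$compartment_labels
  if (spec$compartment_contrast != 1) {
    same <- outer(lab, lab, "==")
    s <- sqrt(spec$compartment_contrast)
    E <- E * ifelse(same, s, 1 / s)
  }
  if (!is.null(spec$tads)) {
    for (k in seq_len(nrow(spec$tads))) {
      idx <- spec$tads$start_bin[k]:spec$tads$end_bin[k]
      E[idx, idx] <- E[idx, idx] * spec$tads$contrast[k]
    }
  }
  if (!is.null(spec$loops)) {
    for (k in seq_len(nrow(spec$loops))) {
      a <- spec$loops$anchor_a[k]; b <- spec$loops$anchor_b[k]
      ia <- intersect((a - 1):(a + 1), seq_len(n))
      ib <- intersect((b - 1):(b + 1), seq_len(n))
      E[ia, ib] <- E[ia, ib] * spec$loops$enrichment[k]
      E[ib, ia] <- E[ib, ia] * spec$loops$enrichment[k]
    }
  }
  if (!is.null(spec$pnh_bins) && spec$pnh_contrast != 1) {
    idx <- spec$pnh_bins
    E[idx, idx] <- E[idx, idx] * spec$pnh_contrast
  }
  if (!is.null(spec$focal_bins) && !is.null(spec$pnh_bins) &&
      spec$focal_contrast != 1) {
    fb <- setdiff(spec$focal_bins, spec$pnh_bins)
    pb <- setdiff(spec$pnh_bins, spec$focal_bins)
    E[fb, pb] <- E[fb, pb] * spec$focal_contrast
    E[pb, fb] <- E[pb, fb] * spec$focal_contrast
  }
  E * spec$depth / sum(E[upper.tri(E, diag = TRUE)])
}

#' Simulate a cis Hi-C contact map
#'
#' Draws Poisson counts around the expected matrix of a
#' [simulation_spec()] (upper triangle, mirrored), and builds the matching
#' GC track and ground-truth record. Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return list with `matrix` (raw [contact_matrix()]), `gc`
#'   ([genome_track()]) and `truth` (planted labels, TAD boundaries, loop
#'   anchors, PNH/focal bins and all contrasts).
#' @export
simulate_hic <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  E <- expected_matrix(spec)
  n <- spec$n_bins
  set.seed(spec$seed)
  ut <- upper.tri(E, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[ut] <- stats::rpois(sum(ut), E[ut])
  counts <- counts + t(counts)
  diag(counts) <- diag(counts) / 2
  m <- contact_matrix(counts, spec$chrom, spec$bin_size, 0, "raw")
  gc <- genome_track(spec$gc_base +
                       spec$gc_delta * (spec$compartment_labels == 1),
                     spec$chrom, spec$bin_size, 0)
  boundaries <- if (is.null(spec$tads)) integer(0)
                else sort(unique(c(spec$tads$start_bin,
                                   spec$tads$end_bin + 1L)))
  truth <- list(compartment_labels = spec$compartment_labels,
                compartment_contrast = spec$compartment_contrast,
                tads = spec$tads, boundaries = boundaries,
                loops = spec$loops,
                pnh_bins = spec$pnh_bins, pnh_contrast = spec$pnh_contrast,
                focal_bins = spec$focal_bins,
                focal_contrast = spec$focal_contrast,
                expected_total = spec$depth, seed = spec$seed)
  list(matrix = m, gc = gc, truth = truth)
}

#' Evenly spaced planted TADs for a simulation
#'
#' Convenience builder: tiles `n_bins` with back-to-back domains of
#' `tad_bins` bins, leaving `margin` bins free at each end.
#'
#' @param n_bins matrix size in bins.
#' @param tad_bins domain length in bins (default 20).
#' @param contrast within-domain contact multiplier (default 2).
#' @param margin bins left free at each end (default 40).
#' @return data.frame `start_bin, end_bin, contrast` usable in
#'   [simulation_spec()].
#' @export
tile_tads <- function(n_bins, tad_bins = 20, contrast = 2, margin = 40) {
  starts <- seq(margin + 1, n_bins - margin - tad_bins + 1, by = tad_bins)
  data.frame(start_bin = starts, end_bin = starts + tad_bins - 1,
             contrast = contrast)
}

#' Simulate stage-patterned expression with planted clusters
#'
#' Each planted cluster's genes peak at one stage (`peak_tpm` there,
#' `base_tpm` elsewhere) with Gaussian noise on the log2 scale; the treated
#' condition shifts each cluster's `log2(TPM + 1)` by its entry in
#' `treatment_shift`. Peak stages are spread evenly across the stage range.
#'
#' @param n_genes_per_cluster genes per planted cluster (default 100).
#' @param stages stage names, or a stage count (default 8).
#' @param noise_sd Gaussian noise sd on the log2 scale (default 0.5).
#' @param treatment_shift per-cluster log2 shift; its length sets the
#'   number of clusters (default `c(1, 0.5, -0.5, -1)`).
#' @param peak_tpm,base_tpm peak and baseline TPM (defaults 100 and 1).
#' @param seed integer seed.
#' @return list with `control` and `treated` (genes x stages TPM
#'   matrices) and `truth` (planted cluster labels and peak stages).
#' @export
simulate_expression <- function(n_genes_per_cluster = 100, stages = 8,
                                noise_sd = 0.5,
                                treatment_shift = c(1, 0.5, -0.5, -1),
                                peak_tpm = 100, base_tpm = 1, seed = 1) {
  if (length(stages) == 1) stages <- paste0("stage", seq_len(stages))
  K <- length(stages)
  if (K < 2) stop("need at least 2 stages")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  k <- length(treatment_shift)
  peak_stage <- round(seq(1, K, length.out = k))
  set.seed(as.integer(seed))
  labels <- rep(seq_len(k), each = n_genes_per_cluster)
  n <- length(labels)
  lg <- matrix(log2(base_tpm + 1), n, K)
  lg[cbind(seq_len(n), peak_stage[labels])] <- log2(peak_tpm + 1)
  lg <- lg + matrix(stats::rnorm(n * K, 0, noise_sd), n, K)
  control <- pmax(2^lg - 1, 0)
  shift <- treatment_shift[labels]
  treated <- pmax(2^(log2(control + 1) + shift) - 1, 0)
  genes <- sprintf("gene_%04d", seq_len(n))
  dimnames(control) <- dimnames(treated) <- list(genes, stages)
  list(control = control, treated = treated,
       truth = list(cluster = labels, peak_stage = peak_stage,
                    treatment_shift = treatment_shift, seed = seed))
}
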