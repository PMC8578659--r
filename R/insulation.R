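#' Insulation score of an O/E matrix
#'
#' For each bin `i`, the raw score is the mean O/E over the square window
#' upstream-by-downstream of the bin: rows `i-w ... i-1` by columns
#' `i+1 ... i+w` (`w = window_bins`, default 5; 40 kb bins by convention).
#' Scores are then normalized against the local background by dividing by
#' the mean raw score of the 50 nearest bins (25 each side, excluding `i`,
#' shrinking at the track ends) and log2-transforming. TAD boundaries are
#' local minima of the normalized track (see [call_boundaries()]).
#'
#' @param oe an O/E [contact_matrix()].
#' @param window_bins window size in bins (default 5).
#' @param norm_bins number of nearest bins in the normalization window
#'   (default 50: 25 each side).
#' @return an object of class `InsulationTrack`: list with `raw` and
#'   `normalized` [genome_track()]s and `window_bins`. Bins whose window
#'   leaves the matrix (the first/last `window_bins` bins) are `NA`.
#' @export
insulation_score <- function(oe, window_bins = 5, norm_bins = 50) {
  stopifnot(inherits(oe, "ContactMatrix"))
  if (oe$kind != "oe") stop("insulation_score expects an O/E matrix")
  if (window_bins < 1) stop("window_bins must be >= 1")
  v <- oe$values
  nb <- nrow(v)
  raw <- rep(NA_real_, nb)
  if (nb >= 2 * window_bins + 1) {
    for (i in (window_bins + 1):(nb - window_bins)) {
      w <- v[(i - window_bins):(i - 1), (i + 1):(i + window_bins), drop = FALSE]
      if (any(!is.na(w))) raw[i] <- mean(w, na.rm = TRUE)
    }
  }
  half <- norm_bins %/% 2
  normalized <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    if (is.na(raw[i])) next
    idx <- setdiff(max(1, i - half):min(nb, i + half), i)
    loc <- mean(raw[idx], na.rm = TRUE)
    if (is.na(loc) || is.nan(loc) || loc <= 0 || raw[i] <= 0) next
    normalized[i] <- log2(raw[i] / loc)
  }
  structure(list(
    raw = genome_track(raw, oe$chrom, oe$bin_size, oe$start_bp),
    normalized = genome_track(normalized, oe$chrom, oe$bin_size, oe$start_bp),
    window_bins = as.integer(window_bins)),
    class = "InsulationTrack")
}

#' @export
print.InsulationTrack <- function(x, ...) {
  cat(sprintf("<InsulationTrack> %s: %d bins, window %d bins, %d defined\n",
              x$raw$chrom, length(x$raw$values), x$window_bins,
              sum(!is.na(x$normalized$values))))
  invisible(x)
}

#' Call TAD boundaries as local minima of normalized insulation
#'
#' A bin is a boundary when its normalized insulation is the minimum over
#' the `+/- local_window` neighborhood and lies below `max_value`.
#'
#' @param ins an [insulation_score()] result.
#' @param local_window neighborhood half-width in bins (default 2).
#' @param max_value call only minima below this normalized value
#'   (default 0: insulation below the local background).
#' @return integer vector of boundary bin indices (1-based).
#' @export
call_boundaries <- function(ins, local_window = 2, max_value = 0) {
  stopifnot(inherits(ins, "InsulationTrack"))
  z <- ins$normalized$values
  nb <- length(z)
  out <- integer(0)
  for (i in seq_len(nb)) {
    if (is.na(z[i]) || z[i] >= max_value) next
    idx <- setdiff(max(1, i - local_window):min(nb, i + local_window), i)
    nbh <- z[idx]
    if (all(is.na(nbh))) next
    if (z[i] <= min(nbh, na.rm = TRUE)) out <- c(out, i)
  }
  out
}

#' Oriented aggregate map around genomic elements
#'
#' Averages O/E submaps centered on a set of stranded elements (e.g.
#' 5'-to-3'-oriented MERVL repeats at TAD boundaries): a window of
#' `flank_bp` each side of the element 5' end is extracted per element,
#' minus-strand submaps are flipped on both axes, and cells are averaged
#' over elements with defined coverage. With 1 Mb flanks at 40 kb bins the
#' result is a 51 x 51 map (2 Mb span).
#'
#' @param oe an O/E [contact_matrix()].
#' @param elements `GRanges` of stranded elements; each is anchored at the
#'   bin containing its 5' end (`start` for `+`/`.`, `end` for `-`).
#' @param flank_bp flank on each side in bp (default 1e6).
#' @param zscore_rows if `TRUE`, each row of the log2 aggregate is
#'   z-scored (rows with zero variance become `NA`).
#' @return an `AggregateMap` (kind `"boundary"`): list with `values`,
#'   `n_elements` (per-cell contributor counts), `n_used`, `n_skipped`.
#' @export
boundary_aggregate <- function(oe, elements, flank_bp = 1e6,
                               zscore_rows = FALSE) {
  stopifnot(inherits(oe, "ContactMatrix"))
  if (oe$kind != "oe") stop("boundary_aggregate expects an O/E matrix")
  chroms <- unique(as.character(GenomicRanges::seqnames(elements)))
  if (!all(chroms == oe$chrom))
    stop("element chromosome(s) do not match matrix chromosome '",
         oe$chrom, "'")
  fb <- as.integer(round(flank_bp / oe$bin_size))
  size <- 2L * fb + 1L
  v <- oe$values
  nb <- nrow(v)
  acc <- matrix(0, size, size)
  cnt <- matrix(0L, size, size)
  used <- 0L; skipped <- 0L
  strand <- as.character(GenomicRanges::strand(elements))
  s0 <- GenomicRanges::start(elements) - 1
  e0 <- GenomicRanges::end(elements)
  for (k in seq_along(elements)) {
    anchor <- if (strand[k] == "-") e0[k] - 1 else s0[k]
    b <- floor((anchor - oe$start_bp) / oe$bin_size) + 1
    if (b - fb < 1 || b + fb > nb) { skipped <- skipped + 1L; next }
    sub <- v[(b - fb):(b + fb), (b - fb):(b + fb), drop = FALSE]
    if (strand[k] == "-") sub <- sub[size:1, size:1, drop = FALSE]
    def <- !is.na(sub)
    sub[!def] <- 0
    acc <- acc + sub
    cnt <- cnt + def
    used <- used + 1L
  }
  if (used == 0L) stop("no usable elements (", skipped, " skipped)")
  vals <- acc / cnt
  vals[cnt == 0L] <- NA_real_
  if (zscore_rows) {
    lg <- log2(vals)
    lg[!is.finite(lg)] <- NA_real_
    vals <- t(apply(lg, 1, function(r) {
      s <- stats::sd(r, na.rm = TRUE)
      if (is.na(s) || s == 0) return(rep(NA_real_, length(r)))
      (r - mean(r, na.rm = TRUE)) / s
    }))
  }
  structure(list(values = vals, n_elements = cnt, kind = "boundary",
                 n_used = used, n_skipped = skipped),
            class = "AggregateMap")
}

#' @export
print.AggregateMap <- function(x, ...) {
  cat(sprintf("<AggregateMap:%s> %d x %d, %d element(s) used, %d skipped\n",
              x$kind, nrow(x$values), ncol(x$values), x$n_used, x$n_skipped))
  invisible(x)
}
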