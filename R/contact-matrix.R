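#' Cis Hi-C contact matrix
#'
#' Container for a single-chromosome (cis) contact matrix at a fixed bin size.
#' Coordinates are 0-based, half-open: bin `b` (1-based index in R) covers
#' `[start_bp + (b-1)*bin_size, start_bp + b*bin_size)`.
#'
#' @param values square symmetric numeric matrix. For `kind = "raw"` entries
#'   must be nonnegative counts; transformed kinds may carry `NA` for
#'   undefined (masked) entries.
#' @param chrom chromosome name (passed through verbatim; never normalized).
#' @param bin_size bin width in base pairs.
#' @param start_bp genomic start of bin 1 (0-based). Default 0.
#' @param kind one of `"raw"`, `"balanced"`, `"oe"`, `"pcc"`.
#' @param mask logical per-bin vector, `TRUE` = bin excluded. Default: no
#'   bins masked.
#'
#' @return an object of class `ContactMatrix` (a list with the above fields).
#' @export
#' @examples
#' m <- contact_matrix(matrix(c(0, 2, 2, 0), 2), "chrS", 150000)
#' n_bins(m)
contact_matrix <- function(values, chrom, bin_size, start_bp = 0,
                           kind = c("raw", "balanced", "oe", "pcc"),
                           mask = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("contact matrix must be square")
  if (is.null(mask)) mask <- rep(FALSE, nrow(values))
  if (length(mask) != nrow(values))
    stop("mask length must equal bin count")
  obj <- structure(
    list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
         start_bp = as.numeric(start_bp), values = values, kind = kind,
         mask = as.logical(mask)),
    class = "ContactMatrix")
  validate_contact_matrix(obj)
  obj
}

validate_contact_matrix <- function(m) {
  v <- m$values
  d <- v - t(v)
  if (max(abs(d), na.rm = TRUE) > 1e-9 && !all(is.na(d)))
    stop("contact matrix is not symmetric (max |M - t(M)| > 1e-9)")
  if (m$kind == "raw") {
    fin <- v[!is.na(v)]
    if (any(fin < 0)) stop("raw counts must be nonnegative")
    if (any(abs(fin - round(fin)) > 1e-9))
      stop("raw counts must be integers")
  }
  if (m$kind == "pcc") {
    fin <- v[!is.na(v)]
    if (length(fin) && (min(fin) < -1 - 1e-9 || max(fin) > 1 + 1e-9))
      stop("pcc entries must lie in [-1, 1]")
  }
  invisible(m)
}

#' @rdname contact_matrix
#' @param m a `ContactMatrix` or `GenomeTrack`.
#' @export
n_bins <- function(m) {
  if (inherits(m, "ContactMatrix")) nrow(m$values) else length(m$values)
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("<ContactMatrix> %s: %d bins x %d bp (%s), %d masked\n",
              x$chrom, n_bins(x), x$bin_size, x$kind, sum(x$mask)))
  invisible(x)
}

#' Per-bin genomic track
#'
#' One value per bin on the same coordinate frame as a [contact_matrix()]
#' (GC fraction, compartment eigenvector, insulation score, ...).
#'
#' @param values numeric vector, one value per bin (`NA` = undefined).
#' @inheritParams contact_matrix
#' @return an object of class `GenomeTrack`.
#' @export
genome_track <- function(values, chrom, bin_size, start_bp = 0) {
  structure(
    list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
         start_bp = as.numeric(start_bp), values = as.numeric(values)),
    class = "GenomeTrack")
}

#' @export
print.GenomeTrack <- function(x, ...) {
  cat(sprintf("<GenomeTrack> %s: %d bins x %d bp\n",
              x$chrom, length(x$values), x$bin_size))
  invisible(x)
}

# Shared frame check for two-matrix operations.
check_same_frame <- function(a, b) {
  if (a$chrom != b$chrom)
    stop("chromosome mismatch: '", a$chrom, "' vs '", b$chrom, "'")
  if (a$bin_size != b$bin_size || n_bins(a) != n_bins(b) ||
      a$start_bp != b$start_bp)
    stop("matrices are not on the same coordinate frame")
  invisible(TRUE)
}

# Map genomic intervals (GRanges, 0-based internally handled) to bin indices.
# Returns the sorted unique 1-based bin indices overlapping any interval.
#' Bins of a contact matrix overlapped by a region set
#'
#' @param m a `ContactMatrix` or `GenomeTrack` giving the coordinate frame.
#' @param regions a `GRanges` region set (as returned by [read_regions()]).
#' @param drop_masked drop bins masked in `m` (default `TRUE`;
#'   ignored for tracks).
#' @return sorted integer vector of 1-based bin indices.
#' @export
region_bins <- function(m, regions, drop_masked = TRUE) {
  chroms <- unique(as.character(GenomicRanges::seqnames(regions)))
  if (length(chroms) == 0) return(integer(0))
  if (!all(chroms == m$chrom))
    stop("region chromosome(s) ", paste(setdiff(chroms, m$chrom), collapse = ","),
         " do not match matrix chromosome '", m$chrom, "'")
  nb <- n_bins(m)
  s0 <- GenomicRanges::start(regions) - 1   # back to 0-based
  e0 <- GenomicRanges::end(regions)         # half-open end
  first <- floor((s0 - m$start_bp) / m$bin_size) + 1
  last <- ceiling((e0 - m$start_bp) / m$bin_size)
  first <- pmax(first, 1L)
  last <- pmin(last, nb)
  keep <- first <= last
  bins <- sort(unique(unlist(mapply(seq, first[keep], last[keep],
                                    SIMPLIFY = FALSE), use.names = FALSE)))
  if (drop_masked && inherits(m, "ContactMatrix"))
    bins <- bins[!m$mask[bins]]
  as.integer(bins)
}
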