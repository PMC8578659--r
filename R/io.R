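# Readers/writers for the plain-text interchange formats: triplet and
# dense contact matrices, BED/BEDPE region sets, bedGraph tracks, JSON
# results. Chromosome names pass through verbatim; a name mismatch between
# a matrix and a region set is an error, never a silent empty join.

#' Read a cis contact matrix
#'
#' Two text formats are supported: triplet lines `bin_i bin_j count`
#' (whitespace-separated, 0-based bins, upper triangle sufficient) and a
#' dense TSV whose header row carries the bin start coordinates.
#'
#' @param path input file.
#' @param chrom chromosome name for the matrix frame.
#' @param bin_size bin width in bp (required for triplet input; inferred
#'   from the header for dense input).
#' @param format `"auto"` (default; sniffs the first line), `"triplet"` or
#'   `"dense"`.
#' @param n_bins matrix size for triplet input (default: largest bin index
#'   + 1).
#' @param start_bp genomic start of bin 0 (default 0).
#' @param kind matrix kind of the stored values (default `"raw"`).
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, chrom, bin_size = NULL,
                                format = c("auto", "triplet", "dense"),
                                n_bins = NULL, start_bp = 0, kind = "raw") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- strsplit(trimws(readLines(path, n = 1)), "[ \t]+")[[1]]
    format <- if (length(first) == 3 &&
                  !anyNA(suppressWarnings(as.numeric(first))))
      "triplet" else "dense"
  }
  if (format == "triplet") {
    if (is.null(bin_size)) stop("bin_size is required for triplet input")
    tri <- data.table::fread(path, header = FALSE,
                             col.names = c("i", "j", "count"))
    if (is.null(n_bins)) n_bins <- max(tri$i, tri$j) + 1
    v <- matrix(0, n_bins, n_bins)
    v[cbind(tri$i + 1, tri$j + 1)] <- tri$count
    v[cbind(tri$j + 1, tri$i + 1)] <- tri$count
  } else {
    dt <- data.table::fread(path, header = TRUE)
    starts <- as.numeric(sub("^[VX]", "", names(dt)))
    if (anyNA(starts)) stop("dense header must carry numeric bin starts")
    v <- as.matrix(dt)
    dimnames(v) <- NULL
    start_bp <- starts[1]
    bin_size <- if (length(starts) > 1) starts[2] - starts[1] else bin_size
  }
  mask <- apply(v, 1, function(r) all(is.na(r)))
  v[is.na(v)] <- if (kind == "raw") 0 else NA_real_
  contact_matrix(v, chrom, bin_size, start_bp, kind,
                 if (kind == "raw") NULL else mask)
}

#' Write a cis contact matrix
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @param format `"triplet"` (nonzero upper triangle incl. diagonal;
#'   0-based bins) or `"dense"` (TSV with bin-start header).
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  v <- m$values
  if (format == "triplet") {
    ut <- which(upper.tri(v, diag = TRUE) & v != 0 & !is.na(v),
                arr.ind = TRUE)
    dt <- data.table::data.table(i = ut[, 1] - 1, j = ut[, 2] - 1,
                                 count = v[ut])
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  } else {
    starts <- m$start_bp + (seq_len(nrow(v)) - 1) * m$bin_size
    dt <- data.table::as.data.table(v)
    data.table::setnames(dt, as.character(starts))
    data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  }
  invisible(path)
}

#' Read a BED3/BED6 region set
#'
#' Tab-separated BED with 0-based half-open coordinates; strand defaults
#' to `"."` when absent. Intervals are NOT merged; a stable sort by
#' (chrom, start) is applied. Malformed lines are reported with their line
#' number.
#'
#' @param path BED file.
#' @return a `GRanges` (1-based internally, as usual for GRanges; strand
#'   and `name` metadata preserved).
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t")
  nf <- lengths(fields)
  if (length(nf) == 0) stop("empty BED file: ", path)
  if (any(nf < 3))
    stop("BED line ", lineno[which(nf < 3)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": start must satisfy 0 <= start < end")
  name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else ".",
                 character(1))
  strand <- vapply(fields, function(f) if (length(f) >= 6) f[6] else "*",
                   character(1))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                               strand = strand, name = name)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a region set as BED6
#'
#' @param gr a `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(gr, path) {
  nm <- if (!is.null(gr$name)) gr$name else "."
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = nm, score = 0, strand = st)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read loop anchor pairs (BEDPE)
#'
#' @param path BEDPE file (`chrom1 start1 end1 chrom2 start2 end2`,
#'   0-based half-open).
#' @return data.frame with those six columns.
#' @export
read_loops <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 6) stop("BEDPE needs at least 6 columns")
  dt <- dt[, 1:6]
  data.table::setnames(dt, c("chrom1", "start1", "end1",
                             "chrom2", "start2", "end2"))
  as.data.frame(dt)
}

#' Read / write a per-bin bedGraph track
#'
#' Delegates parsing/formatting to `rtracklayer`. On read, intervals must
#' tile the expected frame exactly one value per bin.
#'
#' @param path bedGraph file.
#' @param chrom,bin_size,n_bins,start_bp expected frame.
#' @return a [genome_track()].
#' @export
read_bedgraph_track <- function(path, chrom, bin_size, n_bins,
                                start_bp = 0) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  vals <- rep(NA_real_, n_bins)
  b <- floor((GenomicRanges::start(gr) - 1 - start_bp) / bin_size) + 1
  ok <- b >= 1 & b <= n_bins
  vals[b[ok]] <- gr$score[ok]
  genome_track(vals, chrom, bin_size, start_bp)
}

#' @rdname read_bedgraph_track
#' @param track a [genome_track()].
#' @return `path`, invisibly.
#' @export
write_bedgraph_track <- function(track, path) {
  keep <- which(!is.na(track$values))
  starts <- track$start_bp + (keep - 1) * track$bin_size
  gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(starts + 1, starts + track$bin_size),
    score = track$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Intersect a region set with two gating sets
#'
#' Retains the intervals of `a` that overlap (>= 1 bp) at least one
#' interval of `b` AND at least one interval of `c` — e.g. building a
#' peri-nucleolar-heterochromatin set as the L1 intervals supported by
#' both an Inactive Hub and a NAD annotation.
#'
#' @param a,b,c `GRanges` region sets on the same assembly frame.
#' @return the retained subset of `a`.
#' @export
intersect_regions <- function(a, b, c) {
  keep <- IRanges::overlapsAny(a, b, ignore.strand = TRUE) &
    IRanges::overlapsAny(a, c, ignore.strand = TRUE)
  a[keep]
}

# canonical JSON writer for result records (stable field order, no
# timestamps, so reruns under a fixed seed are byte-identical)
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
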