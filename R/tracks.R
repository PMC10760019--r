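# Binned coverage tracks and their normalizations.
#
# A signal_track holds one numeric vector of per-bin values per chromosome
# (bin b covers [(b-1)*bin_size, b*bin_size)), the bin size, the
# normalization tag and, for raw tracks, the total read count used later
# for RPKM/RPM scaling.

#' Construct a binned signal track
#'
#' @param values named list, chromosome -> numeric vector of per-bin
#'   values; each vector must have `ceiling(chrom_length / bin_size)`
#'   entries.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param normalization one of `"raw"`, `"RPKM"`, `"zscore"`, `"RPM"`.
#' @param total_reads total raw read count behind the track; defaults to
#'   the sum of the values for raw tracks.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_sizes,
                         normalization = c("raw", "RPKM", "zscore", "RPM"),
                         total_reads = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(is.list(values), !is.null(names(values)))
  if (!all(names(values) %in% names(chrom_sizes)))
    stop("track chromosome(s) absent from chrom_sizes", call. = FALSE)
  for (chr in names(values)) {
    expect_len <- ceiling(chrom_sizes[[chr]] / bin_size)
    if (length(values[[chr]]) != expect_len)
      stop(sprintf("track %s has %d bins, expected %d", chr,
                   length(values[[chr]]), expect_len), call. = FALSE)
  }
  if (normalization %in% c("raw", "RPKM", "RPM") &&
      any(unlist(values, use.names = FALSE) < 0))
    stop(normalization, " track values must be >= 0", call. = FALSE)
  if (is.null(total_reads))
    total_reads <- if (normalization == "raw")
      sum(unlist(values, use.names = FALSE)) else NA_real_
  structure(list(values = values, bin_size = bin_size,
                 chrom_sizes = chrom_sizes[names(values)],
                 normalization = normalization,
                 total_reads = total_reads),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track [%s]: %d chromosome(s), %d bp bins, %d bins\n",
              x$normalization, length(x$values), x$bin_size,
              length(unlist(x$values, use.names = FALSE))))
  invisible(x)
}

#' RPKM-normalize a raw binned track
#'
#' `RPKM_b = count_b / (bin_kb * total_reads_millions)`: reads per kilobase
#' of bin per million sequenced reads, so doubling depth with all bins
#' doubled leaves the track unchanged.
#'
#' @param raw_track a raw [signal_track()].
#' @param bin expected bin size; a mismatch with the track is an error.
#' @return An RPKM-normalized `signal_track`.
#' @export
rpkm_bins <- function(raw_track, bin = 100) {
  stopifnot(inherits(raw_track, "signal_track"))
  if (raw_track$bin_size != bin)
    stop(sprintf("bin mismatch: track has %d bp bins, expected %d",
                 raw_track$bin_size, bin), call. = FALSE)
  if (raw_track$normalization != "raw")
    stop("rpkm_bins expects a raw track", call. = FALSE)
  n <- raw_track$total_reads
  if (!isTRUE(n > 0)) stop("total reads must be > 0", call. = FALSE)
  scale <- (bin / 1000) * (n / 1e6)
  vals <- lapply(raw_track$values, function(v) v / scale)
  signal_track(vals, bin, raw_track$chrom_sizes, "RPKM", total_reads = n)
}

#' Z-score a track across all its bins
#'
#' @param track a [signal_track()]; typically RPKM.
#' @return A `signal_track` with zero-mean unit-variance values (all-zero
#'   when the track is constant).
#' @export
zscore_track <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  all_v <- unlist(track$values, use.names = FALSE)
  m <- mean(all_v)
  s <- sd(all_v)
  vals <- lapply(track$values, function(v)
    if (s > 0) (v - m) / s else v * 0)
  structure(list(values = vals, bin_size = track$bin_size,
                 chrom_sizes = track$chrom_sizes, normalization = "zscore",
                 total_reads = track$total_reads),
            class = "signal_track")
}

#' Reads-per-million scaling of a raw track
#'
#' @param track a raw [signal_track()].
#' @return `signal_track` with values scaled by `1e6 / total_reads`.
#' @export
rpm_track <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  if (track$normalization != "raw")
    stop("rpm_track expects a raw track", call. = FALSE)
  n <- track$total_reads
  if (!isTRUE(n > 0)) stop("total reads must be > 0", call. = FALSE)
  vals <- lapply(track$values, function(v) v * 1e6 / n)
  signal_track(vals, track$bin_size, track$chrom_sizes, "RPM",
               total_reads = n)
}

#' Import a bedGraph file as a binned track
#'
#' Each bedGraph interval contributes `score * overlap_bp / bin_size` to
#' every bin it covers, so bin-aligned intervals round-trip exactly and
#' uncovered genome is 0.
#'
#' @param path bedGraph file.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param bin_size bin width (bp).
#' @param normalization tag recorded on the resulting track.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size = 100,
                          normalization = "raw") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(names(chrom_sizes), function(chr)
    numeric(ceiling(chrom_sizes[[chr]] / bin_size)))
  names(vals) <- names(chrom_sizes)
  if (length(gr)) {
    chroms <- as.character(GenomeInfoDb::seqnames(gr))
    unknown <- setdiff(unique(chroms), names(chrom_sizes))
    if (length(unknown))
      stop("bedGraph chromosome(s) absent from chrom_sizes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    s0 <- BiocGenerics::start(gr) - 1  # to 0-based half-open
    e0 <- BiocGenerics::end(gr)
    sc <- gr$score
    for (i in seq_along(gr)) {
      b_lo <- floor(s0[i] / bin_size) + 1
      b_hi <- ceiling(e0[i] / bin_size)
      for (b in b_lo:b_hi) {
        ov <- min(e0[i], b * bin_size) - max(s0[i], (b - 1) * bin_size)
        vals[[chroms[i]]][b] <- vals[[chroms[i]]][b] + sc[i] * ov / bin_size
      }
    }
  }
  signal_track(vals, bin_size, chrom_sizes, normalization)
}

#' Write a binned track as bedGraph
#'
#' Adjacent bins with equal values are merged into one interval; zero-value
#' runs are omitted.
#'
#' @param track a [signal_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1
    keep <- r$values != 0
    if (!any(keep)) next
    start_bp <- (starts_bin[keep] - 1) * track$bin_size
    end_bp <- pmin(ends_bin[keep] * track$bin_size,
                   track$chrom_sizes[[chr]])
    writeLines(sprintf("%s\t%d\t%d\t%g", chr, start_bp, end_bp,
                       r$values[keep]), con)
  }
  invisible(path)
}
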