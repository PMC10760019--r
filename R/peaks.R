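# Peak sets: called accessibility peaks with summit offsets.

.peak_cols <- c("peak_id", "chrom", "start", "end", "summit_offset",
                "score", "sample_or_group")

#' Construct a peak set
#'
#' @param df data.frame with columns `chrom, start, end` (0-based
#'   half-open) and optionally `peak_id`, `summit_offset` (bp from peak
#'   start; defaults to the midpoint), `score`, `sample_or_group`.
#' @param sample_or_group label recorded for all peaks when the column is
#'   absent.
#' @return data.frame of class `peak_set`.
#' @export
peak_set <- function(df, sample_or_group = NA_character_) {
  df <- as.data.frame(df)
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop("peak table needs chrom, start, end", call. = FALSE)
  if (is.null(df$peak_id)) df$peak_id <- sprintf("peak_%d", seq_len(nrow(df)))
  if (is.null(df$summit_offset))
    df$summit_offset <- floor((df$end - df$start) / 2)
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$sample_or_group)) df$sample_or_group <- sample_or_group
  if (nrow(df)) {
    if (any(df$start < 0 | df$start >= df$end))
      stop("invalid peak coordinates (need 0 <= start < end)", call. = FALSE)
    bad <- which(df$summit_offset < 0 |
                   df$summit_offset >= df$end - df$start)
    if (length(bad))
      stop(sprintf("summit outside peak for %s", df$peak_id[bad[1]]),
           call. = FALSE)
    if (anyDuplicated(df$peak_id))
      stop("duplicate peak_id", call. = FALSE)
  }
  out <- df[, .peak_cols]
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Read peaks from narrowPeak or BED
#'
#' narrowPeak column 10 is the summit offset from the peak start; a value
#' of -1 (summit not reported) is replaced by the midpoint.  Plain BED
#' input gets midpoint summits.  Coordinates are 0-based half-open as in
#' BED.
#'
#' @param path file path.
#' @param format `"auto"` (by column count), `"narrowPeak"` or `"bed"`.
#' @param sample_or_group label attached to the peaks.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, format = c("auto", "narrowPeak", "bed"),
                       sample_or_group = NA_character_) {
  format <- match.arg(format)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (format == "auto")
    format <- if (ncol(tab) >= 10L) "narrowPeak" else "bed"
  if (format == "narrowPeak" && ncol(tab) < 10L)
    stop("narrowPeak requires 10 columns, got ", ncol(tab), call. = FALSE)
  if (ncol(tab) < 3L) stop("peak file requires >= 3 columns", call. = FALSE)
  width <- tab[[3]] - tab[[2]]
  summit <- if (format == "narrowPeak") tab[[10]] else rep(-1, nrow(tab))
  bad <- which(summit != -1 & (summit < 0 | summit >= width))
  if (length(bad))
    stop(sprintf("summit outside peak at line %d", bad[1]), call. = FALSE)
  summit[summit == -1] <- floor(width[summit == -1] / 2)
  ids <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else
    sprintf("peak_%d", seq_len(nrow(tab)))
  blank <- !nzchar(ids) | ids == "."
  ids[blank] <- sprintf("peak_%d", which(blank))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  score <- if (ncol(tab) >= 5L) tab[[5]] else 0
  peak_set(data.frame(peak_id = ids, chrom = as.character(tab[[1]]),
                      start = tab[[2]], end = tab[[3]],
                      summit_offset = summit, score = score),
           sample_or_group = sample_or_group)
}

# absolute summit position (0-based base)
.summit_pos <- function(peaks) peaks$start + peaks$summit_offset
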