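# Tabular IO: count matrices and sample metadata.

#' Read a feature x sample count/abundance matrix from TSV
#'
#' First column holds feature IDs; remaining columns are samples.  Cells
#' must be numeric and non-negative; for `integer = TRUE` (raw counts)
#' they must also be whole numbers.  Errors report the offending row and
#' column.
#'
#' @param path TSV file with a header line.
#' @param integer require integer values (raw counts).
#' @return Numeric matrix with feature IDs as rownames.
#' @export
read_counts <- function(path, integer = TRUE) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("count table needs >= 2 columns", call. = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicated feature_id: ", ids[duplicated(ids)][1], call. = FALSE)
  mat <- matrix(NA_real_, nrow(tab), ncol(tab) - 1L,
                dimnames = list(ids, names(tab)[-1]))
  for (j in seq_len(ncol(mat))) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(tab[[j + 1L]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s'", bad[1],
                   colnames(mat)[j]), call. = FALSE)
    mat[, j] <- v
  }
  if (anyNA(mat)) stop("missing values in count table", call. = FALSE)
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d, column '%s'", idx[1],
                 colnames(mat)[idx[2]]), call. = FALSE)
  }
  if (integer && any(mat != round(mat))) {
    idx <- which(mat != round(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at row %d, column '%s'", idx[1],
                 colnames(mat)[idx[2]]), call. = FALSE)
  }
  mat
}

#' Write a matrix or data.frame as TSV
#'
#' Matrices are written with rownames in a leading `feature_id` column so
#' that `write_table()` then [read_counts()] round-trips values and
#' ordering exactly.
#'
#' @param x matrix or data.frame.
#' @param path output file.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with at least the columns `sample_id, group, subtype,
#'   cohort`.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "subtype", "cohort")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("metadata lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  tab
}
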