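# Abundance quantification: EM over ambiguous read classes, TPM,
# family-level aggregation, log/z scaling.

#' Construct an abundance matrix
#'
#' A features x samples matrix tagged with its unit and per-feature
#' metadata (feature kind, length and TE family), the common currency of
#' the expression side of the pipeline.
#'
#' @param values numeric matrix (features x samples) with dimnames.
#' @param unit one of `"counts"`, `"TPM"`, `"log2TPM1p"`, `"zscore"`.
#' @param feature_meta optional data.frame with columns `feature_id` and
#'   any of `kind` (`gene`/`te_locus`/`te_family`), `length`, `family`,
#'   `class`; rows are matched to `rownames(values)`.
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values,
                             unit = c("counts", "TPM", "log2TPM1p", "zscore"),
                             feature_meta = NULL) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids", call. = FALSE)
  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta)
    stopifnot("feature_id" %in% names(feature_meta))
    m <- match(rownames(values), feature_meta$feature_id)
    if (anyNA(m))
      stop("feature_meta lacks ",
           rownames(values)[is.na(m)][1], call. = FALSE)
    feature_meta <- feature_meta[m, , drop = FALSE]
    rownames(feature_meta) <- NULL
  }
  structure(list(values = values, unit = unit, feature_meta = feature_meta),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s]: %d features x %d samples\n",
              x$unit, nrow(x$values), ncol(x$values)))
  if (!is.null(x$feature_meta) && "kind" %in% names(x$feature_meta)) {
    tb <- table(x$feature_meta$kind)
    cat("  ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method as.matrix abundance_matrix
#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix by feature kind or class
#'
#' @param x an `abundance_matrix` with `kind` (and optionally `class`)
#'   feature metadata.
#' @param kind feature kinds to keep (`"gene"`, `"te_locus"`,
#'   `"te_family"`).
#' @param class optional gene class filter (`"gene"`, `"kznf"`).
#' @return An `abundance_matrix` with the matching rows.
#' @export
subset_features <- function(x, kind = NULL, class = NULL) {
  stopifnot(inherits(x, "abundance_matrix"), !is.null(x$feature_meta))
  keep <- rep(TRUE, nrow(x$values))
  if (!is.null(kind)) keep <- keep & x$feature_meta$kind %in% kind
  if (!is.null(class)) keep <- keep & x$feature_meta$class %in% class
  abundance_matrix(x$values[keep, , drop = FALSE], x$unit,
                   x$feature_meta[keep, , drop = FALSE])
}

# accept abundance_matrix or plain matrix
.values <- function(x) if (inherits(x, "abundance_matrix")) x$values else x

.feature_meta <- function(x)
  if (inherits(x, "abundance_matrix")) x$feature_meta else NULL

#' EM quantification over ambiguous read classes
#'
#' Resolves multi-mapping ambiguity among features (e.g. TE loci of one
#' family and genes) from read equivalence classes.  Each class is a set
#' of features its reads are equally compatible with, plus a read count.
#' The E-step distributes a class's count across its features
#' proportionally to the current length-corrected abundance
#' `theta_f / length_f`; the M-step re-estimates `theta` from the expected
#' counts; iteration stops when `max |delta theta| < tol`.  The multinomial
#' class log-likelihood is checked to be non-decreasing at every step.
#'
#' @param classes list of elements `list(features = <character>,
#'   count = <number>)`.
#' @param lengths named numeric vector of feature lengths (bp), all > 0;
#'   its names define the feature universe.
#' @param tol convergence tolerance on `theta` (default 1e-8).
#' @param max_iter iteration cap.
#' @return list of class `em_fit` with elements `theta` (read-fraction per
#'   feature), `counts` (expected read counts, summing to the input
#'   total), `tpm`, `loglik` (per-iteration trace), `n_iter`, `converged`.
#' @export
em_quantify <- function(classes, lengths, tol = 1e-8, max_iter = 1000) {
  if (!length(classes)) stop("empty class set", call. = FALSE)
  if (is.null(names(lengths)))
    stop("lengths must be a named vector", call. = FALSE)
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  feats <- names(lengths)
  idx <- lapply(classes, function(cl) {
    if (!length(cl$features)) stop("class with empty feature set",
                                   call. = FALSE)
    i <- match(cl$features, feats)
    if (anyNA(i))
      stop("class references unknown feature: ",
           cl$features[is.na(i)][1], call. = FALSE)
    i
  })
  counts <- vapply(classes, function(cl) as.numeric(cl$count), 0)
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  nf <- length(feats)
  theta <- rep(1 / nf, nf)
  if (total == 0) {
    warning("no reads: returning zero abundances")
    return(structure(list(theta = setNames(rep(0, nf), feats),
                          counts = setNames(rep(0, nf), feats),
                          tpm = setNames(rep(0, nf), feats),
                          loglik = numeric(), n_iter = 0L,
                          converged = TRUE), class = "em_fit"))
  }
  ll_trace <- numeric()
  converged <- FALSE
  it <- 0L
  # read-level mixture model: a read from feature f lands uniformly on
  # its length, so P(read in class c) = sum_{f in c} theta_f / len_f with
  # theta on the simplex; E-step responsibilities are proportional to
  # theta_f / len_f and the M-step averages them (RSEM-style EM)
  while (it < max_iter) {
    it <- it + 1L
    w <- theta / lengths
    expected <- numeric(nf)
    ll <- 0
    for (k in seq_along(idx)) {
      i <- idx[[k]]
      s <- sum(w[i])
      if (counts[k] > 0) {
        if (s > 0) {
          expected[i] <- expected[i] + counts[k] * w[i] / s
          ll <- ll + counts[k] * log(s)
        } else {
          # degenerate: abundance vanished for the whole class
          expected[i] <- expected[i] + counts[k] / length(i)
          ll <- -Inf
        }
      }
    }
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-9)
      stop("EM likelihood decreased: internal error", call. = FALSE)
    ll_trace <- c(ll_trace, ll)
    theta_new <- expected / total
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  rate <- theta / lengths
  tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rate * 0
  structure(list(theta = setNames(theta, feats),
                 counts = setNames(theta * total, feats),
                 tpm = setNames(tpm, feats),
                 loglik = ll_trace, n_iter = it, converged = converged),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("em_fit: %d features, %d iterations (%sconverged)\n",
              length(x$theta), x$n_iter, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' TPM normalization
#'
#' `TPM_fs = (c_fs / len_f) / sum_g(c_gs / len_g) * 1e6`; every column of
#' the result sums to 1e6 (up to rounding) unless it is all-zero, in which
#' case it is left at zero with a warning.
#'
#' @param counts matrix or `abundance_matrix` of non-negative values.
#' @param lengths named vector of feature lengths; taken from the
#'   feature_meta `length` column when omitted.
#' @return `abundance_matrix` with unit `"TPM"`.
#' @export
tpm_normalize <- function(counts, lengths = NULL) {
  meta <- .feature_meta(counts)
  m <- .values(counts)
  if (is.null(lengths)) {
    if (is.null(meta) || !"length" %in% names(meta))
      stop("lengths not supplied and not present in feature_meta",
           call. = FALSE)
    lengths <- setNames(meta$length, meta$feature_id)
  }
  lengths <- lengths[rownames(m)]
  if (anyNA(lengths)) stop("missing length for some features", call. = FALSE)
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  if (any(m < 0)) stop("counts must be >= 0", call. = FALSE)
  rate <- m / lengths
  cs <- colSums(rate)
  zero <- cs == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero column(s) left at zero TPM", sum(zero)))
    cs[zero] <- 1
  }
  tpm <- sweep(rate, 2, cs, "/") * 1e6
  abundance_matrix(tpm, "TPM", meta)
}

#' Aggregate TE locus expression to family level
#'
#' The family value per sample is the arithmetic mean of its member loci
#' in the input unit (the expression-scale reading of family-level
#' averaging).  `method = "log2_mean"` instead averages `log2(x + 1)`
#' across loci and returns unit `"log2TPM1p"`.
#'
#' @param locus_matrix matrix or `abundance_matrix` of TE locus values.
#' @param families named character vector locus -> family; taken from
#'   feature_meta when omitted.  A locus without a family is an error.
#' @param method `"mean"` (expression scale, default) or `"log2_mean"`.
#' @return `abundance_matrix` with one row per family.
#' @export
aggregate_families <- function(locus_matrix, families = NULL,
                               method = c("mean", "log2_mean")) {
  method <- match.arg(method)
  m <- .values(locus_matrix)
  meta <- .feature_meta(locus_matrix)
  if (is.null(families)) {
    if (is.null(meta) || !"family" %in% names(meta))
      stop("families not supplied and not present in feature_meta",
           call. = FALSE)
    families <- setNames(meta$family, meta$feature_id)
  }
  fam <- families[rownames(m)]
  if (anyNA(fam))
    stop("locus without family: ", rownames(m)[is.na(fam)][1], call. = FALSE)
  vals <- if (method == "log2_mean") log2(m + 1) else m
  sums <- rowsum(vals, fam)
  n <- as.vector(table(fam)[rownames(sums)])
  out <- sums / n
  unit <- if (inherits(locus_matrix, "abundance_matrix")) {
    if (method == "log2_mean") "log2TPM1p" else locus_matrix$unit
  } else if (method == "log2_mean") "log2TPM1p" else "TPM"
  fam_meta <- data.frame(feature_id = rownames(out), kind = "te_family",
                         length = NA_real_, family = rownames(out))
  abundance_matrix(out, unit, fam_meta)
}

#' Log-transform and per-feature z-score
#'
#' `log2(x + pseudocount)` followed by z-scoring each feature across
#' samples; constant features map to all-zero rows.
#'
#' @param matrix matrix or `abundance_matrix` of non-negative values
#'   (typically TPM).
#' @param pseudocount added before the log (default 1).
#' @return `abundance_matrix` with unit `"zscore"`.
#' @export
log_zscale <- function(matrix, pseudocount = 1) {
  m <- .values(matrix)
  if (any(m < 0)) stop("log_zscale expects non-negative values",
                       call. = FALSE)
  lg <- log2(m + pseudocount)
  mu <- rowMeans(lg)
  s <- apply(lg, 1, sd)
  z <- (lg - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  abundance_matrix(z, "zscore", .feature_meta(matrix))
}
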