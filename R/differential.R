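# Rank-based differential expression and cluster-marker detection.

.resolve_labels <- function(labels, mat) {
  if (!is.null(names(labels))) {
    m <- match(colnames(mat), names(labels))
    if (anyNA(m))
      stop("labels missing for sample(s): ",
           paste(colnames(mat)[is.na(m)], collapse = ", "), call. = FALSE)
    labels <- labels[m]
  } else if (length(labels) != ncol(mat)) {
    stop("labels length does not match sample count", call. = FALSE)
  }
  as.character(labels)
}

# log2 fold change of group means; ratio with pseudocount when the data
# are non-negative (expression scale), plain mean difference otherwise
# (already-log or z-scored input).
.lfc <- function(xa, xb, pseudocount, nonneg) {
  if (nonneg) log2((mean(xa) + pseudocount) / (mean(xb) + pseudocount))
  else mean(xa) - mean(xb)
}

.wilcox_row <- function(xa, xb) {
  if (length(unique(c(xa, xb))) == 1L)
    return(c(stat = length(xa) * length(xb) / 2, p = 1))
  use_exact <- (length(xa) + length(xb)) <= 12 &&
    !anyDuplicated(c(xa, xb))
  wt <- suppressWarnings(
    wilcox.test(xa, xb, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  c(stat = unname(wt$statistic), p = wt$p.value)
}

#' Wilcoxon rank-sum differential expression between two groups
#'
#' Two-sided Mann-Whitney test per feature with mid-rank ties; exact
#' enumeration when `nA + nB <= 12` and there are no ties, otherwise the
#' normal approximation with tie and continuity correction.  Fold change
#' is mean-based with a pseudocount (1 in TPM units by default).
#'
#' @param matrix features x samples matrix or `abundance_matrix`.
#' @param labels group label per sample (named by sample or aligned to
#'   columns).
#' @param groupA,groupB the two groups to compare; `lfc > 0` means higher
#'   in `groupA`.
#' @param correction `"bonferroni"` (default, `padj = min(1, m p)`),
#'   `"BH"` or `"none"`.
#' @param pseudocount added to group means in the fold change.
#' @return data.frame of class `differential_result`: `feature_id, lfc,
#'   stat, p, padj, direction, group_a, group_b`.
#' @export
wilcoxon_de <- function(matrix, labels, groupA, groupB,
                        correction = c("bonferroni", "BH", "none"),
                        pseudocount = 1) {
  correction <- match.arg(correction)
  m <- .values(matrix)
  labels <- .resolve_labels(labels, m)
  for (g in c(groupA, groupB))
    if (!g %in% labels) stop("group absent from labels: ", g, call. = FALSE)
  ia <- labels == groupA
  ib <- labels == groupB
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  nonneg <- min(m) >= 0
  res <- t(vapply(seq_len(nrow(m)), function(i)
    .wilcox_row(m[i, ia], m[i, ib]), c(stat = 0, p = 0)))
  lfc <- vapply(seq_len(nrow(m)), function(i)
    .lfc(m[i, ia], m[i, ib], pseudocount, nonneg), 0)
  padj <- switch(correction,
                 bonferroni = pmin(1, res[, "p"] * nrow(m)),
                 BH = p.adjust(res[, "p"], "BH"),
                 none = res[, "p"])
  out <- data.frame(feature_id = rownames(m), lfc = lfc,
                    stat = res[, "stat"], p = res[, "p"], padj = padj,
                    direction = sign(lfc), group_a = groupA,
                    group_b = groupB, row.names = NULL)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' One-vs-rest cluster markers by Kruskal-Wallis
#'
#' For every cluster, each feature is tested with the Kruskal-Wallis rank
#' test (with tie correction) on the two groups cluster-vs-rest -- for two
#' groups this is the squared standardized Wilcoxon statistic on 1 df.
#' P-values are BH-adjusted within each cluster's feature list; a marker
#' is a feature at `padj < fdr` with positive fold change versus the rest.
#'
#' @param matrix features x samples matrix or `abundance_matrix`.
#' @param cluster_labels cluster per sample (named or column-aligned);
#'   every cluster needs >= 2 samples.
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @param fdr marker threshold on adjusted p (default 0.05).
#' @param pseudocount for the fold change.
#' @return data.frame with columns `cluster, feature_id, lfc, stat, p,
#'   padj, marker`.
#' @export
cluster_markers <- function(matrix, cluster_labels, correction = "BH",
                            fdr = 0.05, pseudocount = 1) {
  m <- .values(matrix)
  labels <- .resolve_labels(cluster_labels, m)
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 clusters", call. = FALSE)
  if (any(tab < 2))
    stop("singleton cluster: ", names(tab)[tab < 2][1], call. = FALSE)
  nonneg <- min(m) >= 0
  out <- lapply(names(tab), function(cl) {
    grp <- factor(ifelse(labels == cl, "in", "out"))
    stats_p <- t(vapply(seq_len(nrow(m)), function(i) {
      x <- m[i, ]
      if (length(unique(x)) == 1L) return(c(stat = 0, p = 1))
      kt <- kruskal.test(x, grp)
      c(stat = unname(kt$statistic), p = kt$p.value)
    }, c(stat = 0, p = 0)))
    lfc <- vapply(seq_len(nrow(m)), function(i)
      .lfc(m[i, labels == cl], m[i, labels != cl], pseudocount, nonneg), 0)
    padj <- if (correction == "BH") p.adjust(stats_p[, "p"], "BH")
            else pmin(1, stats_p[, "p"] * nrow(m))
    data.frame(cluster = cl, feature_id = rownames(m), lfc = lfc,
               stat = stats_p[, "stat"], p = stats_p[, "p"], padj = padj,
               marker = padj < fdr & lfc > 0, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Select the most variable features
#'
#' Ranks features by variance across samples (on the supplied, typically
#' log-scale, matrix) and returns the top `n_features` IDs; ties break
#' deterministically by feature ID.
#'
#' @param matrix features x samples matrix or `abundance_matrix`.
#' @param n_features number of features to return; values above the
#'   feature count return everything with a warning.
#' @return Character vector of feature IDs, most variable first.
#' @export
select_variable <- function(matrix, n_features) {
  m <- .values(matrix)
  if (n_features > nrow(m)) {
    warning("n_features exceeds feature count; returning all features")
    n_features <- nrow(m)
  }
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  head(rownames(m)[ord], n_features)
}
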