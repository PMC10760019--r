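# Population-specific cis-regulatory TE-gene pair calling: TE-associated
# differential accessibility combined with proximal differential
# expression.

#' Per-peak signal matrix from sample tracks
#'
#' Summarizes each sample's normalized track over every peak as the mean
#' of the bins the peak touches, yielding the peaks x samples matrix that
#' [diff_accessibility()] tests.
#'
#' @param tracks named list, sample -> [signal_track()].
#' @param peaks a [peak_set()].
#' @return numeric matrix (peaks x samples).
#' @export
peak_signal_matrix <- function(tracks, peaks) {
  out <- vapply(names(tracks), function(s) {
    tr <- tracks[[s]]
    vapply(seq_len(nrow(peaks)), function(i) {
      chr <- peaks$chrom[i]
      if (!chr %in% names(tr$values)) return(NA_real_)
      v <- tr$values[[chr]]
      bins <- .bins_for_interval(peaks$start[i], peaks$end[i], tr$bin_size)
      bins <- bins[bins >= 1 & bins <= length(v)]
      mean(v[bins])
    }, 0)
  }, numeric(nrow(peaks)))
  rownames(out) <- peaks$peak_id
  out
}

#' Differential accessibility between two groups
#'
#' Wilcoxon rank-sum test per peak on normalized per-peak signal, with a
#' mean-based log2 fold change (pseudocount on the expression-like scale;
#' mean difference for signed inputs such as z-scores).
#'
#' @param peak_matrix peaks x samples matrix of normalized signal (e.g.
#'   [peak_signal_matrix()] on RPKM tracks).
#' @param labels group per sample (named or column-aligned).
#' @param A,B groups to compare; `lfc > 0` means more accessible in `A`.
#' @param pseudocount for the fold change (default 0.5, RPKM-scale).
#' @return data.frame `peak_id, lfc, stat, p`.
#' @export
diff_accessibility <- function(peak_matrix, labels, A, B,
                               pseudocount = 0.5) {
  de <- wilcoxon_de(peak_matrix, labels, A, B, correction = "none",
                    pseudocount = pseudocount)
  data.frame(peak_id = de$feature_id, lfc = de$lfc, stat = de$stat,
             p = de$p)
}

# unsigned distance between a TSS base and a 0-based half-open interval;
# 0 when the TSS lies inside
.tss_interval_dist <- function(tss, start, end) {
  ifelse(tss >= start & tss < end, 0,
         ifelse(tss >= end, tss - end, start - tss))
}

#' Link TE-associated peaks to nearby TSSs
#'
#' Pairs each peak with every gene whose TSS lies within `max_dist` of
#' the peak interval (distance 0 when the TSS is inside the peak;
#' boundary inclusive).  The signed summit-to-TSS distance is reported
#' for ranking: positive when the TSS is downstream of the summit on the
#' genome axis.
#'
#' @param te_peaks a [peak_set()], typically pre-filtered to TE-associated
#'   peaks via [peak_te_overlap()].
#' @param genes gene table (or a [genome_annotation()]).
#' @param max_dist maximum interval-to-TSS distance in bp (default
#'   10000).
#' @return data.frame `peak_id, gene_id, distance, summit_tss_dist`.
#' @export
link_peaks_to_tss <- function(te_peaks, genes, max_dist = 10000) {
  if (inherits(genes, "genome_annotation")) genes <- genes$genes
  out <- list()
  summit <- .summit_pos(te_peaks)
  for (chr in intersect(unique(te_peaks$chrom), unique(genes$chrom))) {
    pi <- which(te_peaks$chrom == chr)
    gi <- which(genes$chrom == chr)
    for (i in pi) {
      d <- .tss_interval_dist(genes$tss[gi], te_peaks$start[i],
                              te_peaks$end[i])
      keep <- which(d <= max_dist)
      if (!length(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        peak_id = te_peaks$peak_id[i],
        gene_id = genes$gene_id[gi[keep]],
        distance = d[keep],
        summit_tss_dist = genes$tss[gi[keep]] - summit[i])
    }
  }
  if (!length(out))
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric(), summit_tss_dist = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call putative population-specific cis-regulatory TE-gene pairs
#'
#' A candidate (peak, gene) pair is emitted when the peak passes the
#' differential-accessibility thresholds (nominal p and |lfc|), the gene
#' passes the differential-expression threshold (adjusted p as supplied
#' by the caller's [wilcoxon_de()] run), and (by default) the two effects
#' point in the same direction.  Output is sorted by gene then distance.
#'
#' @param candidates data.frame from [link_peaks_to_tss()].
#' @param access_stats data.frame from [diff_accessibility()]; every
#'   candidate peak must be present.
#' @param expr_stats a [wilcoxon_de()] result; every candidate gene must
#'   be present.
#' @param thresholds list with elements `access_p` (default 0.05),
#'   `access_lfc` (default 0.5), `expr_padj` (default 0.05),
#'   `require_concordance` (default TRUE).
#' @param te_overlap optional [peak_te_overlap()] table used to attach
#'   the underlying TE locus/family to each pair (one output row per
#'   qualifying locus).
#' @param contrast label recorded on the output (e.g. `"EC_vs_HC"`).
#' @return data.frame of class `cisreg_pairs`: `locus_id, peak_id,
#'   gene_id, distance, summit_tss_dist, access_lfc, access_p, expr_lfc,
#'   expr_padj, concordant, contrast`.
#' @export
call_cisreg_pairs <- function(candidates, access_stats, expr_stats,
                              thresholds = list(), te_overlap = NULL,
                              contrast = NA_character_) {
  th <- utils::modifyList(list(access_p = 0.05, access_lfc = 0.5,
                               expr_padj = 0.05,
                               require_concordance = TRUE),
                          thresholds)
  empty <- data.frame(locus_id = character(), peak_id = character(),
                      gene_id = character(), distance = numeric(),
                      summit_tss_dist = numeric(), access_lfc = numeric(),
                      access_p = numeric(), expr_lfc = numeric(),
                      expr_padj = numeric(), concordant = logical(),
                      contrast = character())
  class(empty) <- c("cisreg_pairs", "data.frame")
  if (!nrow(candidates)) return(empty)
  am <- match(candidates$peak_id, access_stats$peak_id)
  if (anyNA(am))
    stop("candidate peak without accessibility stats: ",
         candidates$peak_id[is.na(am)][1], call. = FALSE)
  em <- match(candidates$gene_id, expr_stats$feature_id)
  if (anyNA(em))
    stop("candidate gene without expression stats: ",
         candidates$gene_id[is.na(em)][1], call. = FALSE)
  df <- data.frame(candidates,
                   access_lfc = access_stats$lfc[am],
                   access_p = access_stats$p[am],
                   expr_lfc = expr_stats$lfc[em],
                   expr_padj = expr_stats$padj[em])
  df$concordant <- sign(df$access_lfc) == sign(df$expr_lfc) &
    df$access_lfc != 0
  keep <- df$access_p < th$access_p &
    abs(df$access_lfc) >= th$access_lfc &
    df$expr_padj < th$expr_padj
  if (isTRUE(th$require_concordance)) keep <- keep & df$concordant
  df <- df[keep, , drop = FALSE]
  if (!is.null(te_overlap) && nrow(df)) {
    lk <- te_overlap[, c("peak_id", "locus_id")]
    df <- merge(df, lk, by = "peak_id")
  } else {
    df$locus_id <- rep(NA_character_, nrow(df))
  }
  df$contrast <- rep(contrast, nrow(df))
  if (nrow(df)) df <- df[order(df$gene_id, df$distance), ]
  cols <- names(empty)
  df <- df[, cols]
  rownames(df) <- NULL
  class(df) <- c("cisreg_pairs", "data.frame")
  df
}
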