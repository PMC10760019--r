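# Peak-TE overlap, family enrichment against a size-matched random null,
# metaprofiles and per-cluster family accessibility.

# all-pairs interval intersections between two 0-based half-open tables,
# per chromosome, via IRanges; returns row indices into each table plus
# the overlap width in bp
.interval_overlaps <- function(a, b) {
  out <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    ir_a <- IRanges::IRanges(start = a$start[ai] + 1, end = a$end[ai])
    ir_b <- IRanges::IRanges(start = b$start[bi] + 1, end = b$end[bi])
    hits <- IRanges::findOverlaps(ir_a, ir_b)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ir_a[qi], ir_b[si]))
    out[[chr]] <- data.frame(a_idx = ai[qi], b_idx = bi[si],
                             overlap_bp = ov)
  }
  if (!length(out))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = numeric()))
  do.call(rbind, out)
}

#' Overlap peaks with TE loci
#'
#' Computes all (peak, TE locus) intersections and retains pairs where the
#' TE covers at least `min_frac` of the peak (the fraction-of-peak reading
#' of the 50% threshold) and, when `require_summit` is set, the peak
#' summit lies inside the TE interval.  A peak may be retained with
#' several loci.
#'
#' @param peaks a [peak_set()].
#' @param te_loci TE locus table (or a [genome_annotation()]).
#' @param min_frac minimum overlap as a fraction of the peak width
#'   (boundary inclusive; default 0.5).
#' @param require_summit additionally require the summit inside the TE.
#' @return data.frame of class `overlap_table`: `peak_id, locus_id,
#'   subfamily, family, overlap_bp, overlap_frac_of_peak, summit_in_te`.
#' @export
peak_te_overlap <- function(peaks, te_loci, min_frac = 0.5,
                            require_summit = TRUE) {
  if (inherits(te_loci, "genome_annotation")) te_loci <- te_loci$te_loci
  hits <- .interval_overlaps(peaks, te_loci)
  if (!nrow(hits)) {
    out <- data.frame(peak_id = character(), locus_id = character(),
                      subfamily = character(), family = character(),
                      overlap_bp = numeric(),
                      overlap_frac_of_peak = numeric(),
                      summit_in_te = logical())
    class(out) <- c("overlap_table", "data.frame")
    return(out)
  }
  pw <- peaks$end[hits$a_idx] - peaks$start[hits$a_idx]
  frac <- hits$overlap_bp / pw
  summit <- .summit_pos(peaks)[hits$a_idx]
  in_te <- summit >= te_loci$start[hits$b_idx] &
    summit < te_loci$end[hits$b_idx]
  out <- data.frame(peak_id = peaks$peak_id[hits$a_idx],
                    locus_id = te_loci$locus_id[hits$b_idx],
                    subfamily = te_loci$subfamily[hits$b_idx],
                    family = te_loci$family[hits$b_idx],
                    overlap_bp = hits$overlap_bp,
                    overlap_frac_of_peak = frac,
                    summit_in_te = in_te)
  keep <- out$overlap_frac_of_peak >= min_frac
  if (require_summit) keep <- keep & out$summit_in_te
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("overlap_table", "data.frame")
  out
}

# place each peak at a uniform random genome position, width preserved,
# summit offset carried over; optionally avoiding `exclude` regions
.random_peaks <- function(peaks, chrom_sizes, exclude = NULL,
                          max_tries = 200) {
  widths <- peaks$end - peaks$start
  if (any(vapply(widths, function(w) all(chrom_sizes < w), TRUE)))
    stop("peak wider than every chromosome", call. = FALSE)
  n <- nrow(peaks)
  chr <- character(n)
  start <- numeric(n)
  if (is.null(exclude) || !nrow(exclude)) {
    # vectorized uniform placement: chromosome with probability
    # proportional to available positions, then uniform start
    avail <- vapply(names(chrom_sizes), function(cn)
      pmax(chrom_sizes[[cn]] - widths + 1, 0), numeric(n))
    avail <- matrix(avail, nrow = n,
                    dimnames = list(NULL, names(chrom_sizes)))
    tot <- rowSums(avail)
    if (any(tot == 0))
      stop("peak wider than every chromosome", call. = FALSE)
    cum <- avail
    if (ncol(cum) > 1)
      for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1]
    u <- runif(n) * tot
    ci <- rowSums(u > cum) + 1L
    chr <- colnames(avail)[ci]
    start <- floor(runif(n) * avail[cbind(seq_len(n), ci)])
    df <- data.frame(peak_id = peaks$peak_id, chrom = chr, start = start,
                     end = start + widths,
                     summit_offset = peaks$summit_offset,
                     score = peaks$score,
                     sample_or_group = peaks$sample_or_group)
    class(df) <- c("peak_set", "data.frame")
    return(df)
  }
  for (i in seq_len(n)) {
    a <- pmax(chrom_sizes - widths[i] + 1, 0)
    for (try in seq_len(max_tries)) {
      ci <- sample.int(length(chrom_sizes), 1, prob = a / sum(a))
      s <- floor(runif(1) * a[ci])
      if (!is.null(exclude) && nrow(exclude)) {
        cand <- data.frame(chrom = names(chrom_sizes)[ci], start = s,
                           end = s + widths[i])
        if (nrow(.interval_overlaps(cand, exclude))) next
      }
      chr[i] <- names(chrom_sizes)[ci]
      start[i] <- s
      break
    }
    if (!nzchar(chr[i]))
      stop("could not place random peak outside excluded regions",
           call. = FALSE)
  }
  df <- data.frame(peak_id = peaks$peak_id, chrom = chr, start = start,
                   end = start + widths,
                   summit_offset = peaks$summit_offset,
                   score = peaks$score,
                   sample_or_group = peaks$sample_or_group)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' TE-family enrichment of peaks versus a size-matched random null
#'
#' Counts, per TE family, the peaks that pass the overlap rule
#' ([peak_te_overlap()]) with at least one locus of the family, then
#' repeats the count `n_draws` times with every peak replaced by a
#' uniformly placed interval of identical width (and summit offset).
#' Enrichment is `log2((observed + eps) / (expected + eps))` with
#' `expected` the mean over draws, and the empirical p-value for
#' enrichment is `(1 + #draws >= observed) / (n_draws + 1)` (`<=` for
#' depletion).
#'
#' @param peaks a [peak_set()].
#' @param annotation a [genome_annotation()] (needs chrom_sizes and
#'   te_loci).
#' @param n_draws random draws (default 100).
#' @param seed RNG seed.
#' @param exclude optional data.frame `chrom, start, end` of regions
#'   random peaks must avoid (e.g. unmappable genome).
#' @param min_frac,require_summit overlap rule, as [peak_te_overlap()].
#' @param eps pseudocount in the log2 ratio (default 0.5).
#' @return data.frame of class `enrichment_result`: per family the
#'   observed count, expected mean and sd, `log2_ratio`, `p_enrich`,
#'   `p_deplete`.
#' @export
family_enrichment <- function(peaks, annotation, n_draws = 100, seed = 1,
                              exclude = NULL, min_frac = 0.5,
                              require_summit = TRUE, eps = 0.5) {
  stopifnot(inherits(annotation, "genome_annotation"))
  te <- annotation$te_loci
  families <- sort(unique(te$family))
  count_by_family <- function(p) {
    ov <- peak_te_overlap(p, te, min_frac = min_frac,
                          require_summit = require_summit)
    cnt <- setNames(numeric(length(families)), families)
    if (nrow(ov)) {
      u <- unique(ov[, c("peak_id", "family")])
      tb <- table(u$family)
      cnt[names(tb)] <- as.numeric(tb)
    }
    cnt
  }
  observed <- count_by_family(peaks)
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      count_by_family(.random_peaks(peaks, annotation$chrom_sizes,
                                    exclude = exclude))
    }, numeric(length(families)))
  })
  draws <- matrix(draws, nrow = length(families),
                  dimnames = list(families, NULL))
  expected <- rowMeans(draws)
  exp_sd <- apply(draws, 1, sd)
  p_enrich <- (1 + rowSums(draws >= observed)) / (n_draws + 1)
  p_deplete <- (1 + rowSums(draws <= observed)) / (n_draws + 1)
  out <- data.frame(family = families, observed = as.numeric(observed),
                    expected = expected, expected_sd = exp_sd,
                    log2_ratio = log2((observed + eps) / (expected + eps)),
                    p_enrich = p_enrich, p_deplete = p_deplete,
                    n_draws = n_draws, row.names = NULL)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# bins of a track overlapping [start, end), as indices per chromosome
.bins_for_interval <- function(start, end, bin_size) {
  (floor(start / bin_size) + 1):ceiling(end / bin_size)
}

#' Accessibility metaprofile around TE family loci
#'
#' Averages per-group signal in `2 * window / bin + 1` bins anchored at
#' each locus's left boundary (the lower genomic coordinate, regardless
#' of strand).  Raw tracks are scaled to reads per million first; windows
#' truncated by chromosome ends contribute missing values that are
#' excluded from the means.
#'
#' @param tracks named list, group/cluster -> [signal_track()].
#' @param family_loci data.frame of the family's loci (rows of a te_loci
#'   table); must be non-empty.
#' @param window half-window in bp (default 5000); must be divisible by
#'   `bin`.
#' @param bin bin width (bp); must equal the tracks' bin size.
#' @return matrix groups x bins of mean signal, with the bin-start offsets
#'   (bp, relative to the anchor) as an `offsets` attribute.
#' @export
metaprofile <- function(tracks, family_loci, window = 5000, bin = 100) {
  if (!nrow(family_loci))
    stop("family has 0 loci: ",
         paste(unique(family_loci$family), collapse = ","), call. = FALSE)
  if (window %% bin != 0)
    stop("window must be divisible by bin", call. = FALSE)
  offsets <- seq(-window, window, by = bin)
  prof <- t(vapply(names(tracks), function(g) {
    tr <- tracks[[g]]
    if (tr$bin_size != bin)
      stop(sprintf("bin mismatch: track '%s' has %d bp bins, expected %d",
                   g, tr$bin_size, bin), call. = FALSE)
    if (tr$normalization == "raw") tr <- rpm_track(tr)
    vals <- matrix(NA_real_, nrow(family_loci), length(offsets))
    for (i in seq_len(nrow(family_loci))) {
      chr <- family_loci$chrom[i]
      if (!chr %in% names(tr$values)) next
      v <- tr$values[[chr]]
      pos <- family_loci$start[i] + offsets
      bidx <- floor(pos / bin) + 1
      ok <- pos >= 0 & bidx <= length(v)
      vals[i, ok] <- v[bidx[ok]]
    }
    colMeans(vals, na.rm = TRUE)
  }, numeric(length(offsets))))
  colnames(prof) <- offsets
  attr(prof, "offsets") <- offsets
  prof
}

#' Mean family accessibility per sample and cluster
#'
#' For each sample, averages the track over all bins overlapping the
#' family's loci; sample means are then averaged within clusters.
#'
#' @param tracks named list, sample -> normalized [signal_track()].
#' @param family_loci data.frame of the family's loci.
#' @param cluster_labels cluster per sample (named by sample).
#' @return data.frame `cluster, mean, sd, n_samples`; clusters without
#'   any track are reported as NA.
#' @export
family_accessibility_by_cluster <- function(tracks, family_loci,
                                            cluster_labels) {
  if (!nrow(family_loci)) stop("family has 0 loci", call. = FALSE)
  sample_mean <- vapply(names(tracks), function(s) {
    tr <- tracks[[s]]
    acc <- c()
    for (chr in unique(family_loci$chrom)) {
      if (!chr %in% names(tr$values)) next
      rows <- family_loci$chrom == chr
      bins <- unique(unlist(mapply(.bins_for_interval,
                                   family_loci$start[rows],
                                   family_loci$end[rows],
                                   MoreArgs = list(bin_size = tr$bin_size),
                                   SIMPLIFY = FALSE)))
      bins <- bins[bins >= 1 & bins <= length(tr$values[[chr]])]
      acc <- c(acc, tr$values[[chr]][bins])
    }
    mean(acc)
  }, 0)
  clusters <- sort(unique(cluster_labels))
  out <- do.call(rbind, lapply(clusters, function(cl) {
    s <- names(cluster_labels)[cluster_labels == cl]
    s <- intersect(s, names(sample_mean))
    if (!length(s))
      return(data.frame(cluster = cl, mean = NA_real_, sd = NA_real_,
                        n_samples = 0L))
    data.frame(cluster = cl, mean = mean(sample_mean[s]),
               sd = if (length(s) > 1) sd(sample_mean[s]) else NA_real_,
               n_samples = length(s))
  }))
  rownames(out) <- NULL
  out
}
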