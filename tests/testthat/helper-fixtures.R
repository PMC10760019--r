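# Shared fixture builders; everything is generated in code at test time.

# small deterministic annotation: 1 chromosome, two families, a few genes
toy_annotation <- function() {
  genome_annotation(
    chrom_sizes = c(chr1 = 100000),
    te_loci = data.frame(
      locus_id = c("MER41B.1", "MER41B.2", "LTR12C.1"),
      chrom = "chr1",
      start = c(1000, 5000, 20000),
      end = c(1600, 5600, 21500),
      strand = c("+", "-", "+"),
      subfamily = c("MER41B", "MER41B", "LTR12C"),
      family = c("MER41", "LTR12", "LTR12")[c(1, 1, 2)]),
    genes = data.frame(
      gene_id = c("GBP2", "HCP5", "ZNF534"),
      chrom = "chr1",
      tss = c(2500, 25000, 80000),
      strand = c("+", "-", "+"),
      class = c("gene", "gene", "kznf")))
}

# uniformly placed peaks on a single-chromosome genome
uniform_peaks <- function(seed, n, width, chrom_len, chrom = "chr1") {
  with_seed(seed, {
    start <- floor(runif(n) * (chrom_len - width))
    peak_set(data.frame(peak_id = sprintf("u%d", seq_len(n)),
                        chrom = chrom, start = start,
                        end = start + width))
  })
}

# brute-force all-pairs peak/TE overlap with the 50%-of-peak + summit rule
brute_overlap <- function(peaks, te, min_frac = 0.5,
                          require_summit = TRUE) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(te))) {
      if (peaks$chrom[i] != te$chrom[j]) next
      ov <- min(peaks$end[i], te$end[j]) - max(peaks$start[i], te$start[j])
      if (ov <= 0) next
      frac <- ov / (peaks$end[i] - peaks$start[i])
      summit <- peaks$start[i] + peaks$summit_offset[i]
      s_in <- summit >= te$start[j] && summit < te$end[j]
      if (frac >= min_frac && (!require_summit || s_in))
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], locus_id = te$locus_id[j],
          overlap_bp = ov, frac = frac, summit_in_te = s_in)
    }
  }
  if (!length(out)) return(data.frame(peak_id = character(),
                                      locus_id = character()))
  do.call(rbind, out)
}

# brute-force exact two-sided Wilcoxon p by enumerating all assignments
brute_wilcox_p <- function(x, y) {
  n <- length(x) + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combs <- utils::combn(n, length(x))
  w_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - length(x) * (length(x) + 1) / 2)
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

# brute-force BH step-up rejection set at level alpha
brute_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i / m * alpha) k <- i
  if (k == 0) return(logical(m))
  p <= p[ord[k]]
}
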