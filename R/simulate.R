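# Synthetic-data generators.  Every simulator is a pure function of its
# inputs and seed (RNG state is saved and restored), and returns the
# planted ground truth alongside the realization.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so simulators are pure functions of
#' `(inputs, seed)` and do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @export
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Describe a simulated study design
#'
#' Collects the parameters that the simulators
#' ([simulate_counts()], [simulate_atac()]) realize: per-group sample
#' sizes, planted cluster structure, planted differential features,
#' negative-binomial dispersion, library sizes, latent-factor KZNF-TE
#' couplings, and planted accessible TE loci with their linked genes.
#'
#' @param n_samples named integer vector of samples per group; groups are
#'   a subset of `EC, HC, VP, ART`.
#' @param cluster_labels optional cluster label per sample: either a named
#'   vector (sample_id -> cluster) or an unnamed vector over all samples
#'   in group order.
#' @param de optional data.frame of planted differential features with
#'   columns `feature_id, lfc` and one of `group` / `cluster` naming the
#'   affected samples (log2 fold-change applied to the NB mean).
#' @param dispersion NB dispersion (scalar, or named per-feature); the
#'   variance is `mu + dispersion * mu^2`.
#' @param library_sizes per-sample relative depth (scalar or named
#'   vector; default 1).
#' @param base_mean_range range of per-feature baseline means, drawn
#'   log-uniform.
#' @param kznf_pairs optional data.frame `kznf_id, family, rho` of planted
#'   KZNF -> TE-family couplings; `rho` is the target magnitude of the
#'   negative rank correlation, realized through a shared per-sample
#'   latent factor entering the KZNF mean positively and the family's
#'   locus means negatively.
#' @param accessible_te optional data.frame `locus_id, gene_id, lfc,
#'   group` of planted accessible TE loci, their linked genes, the
#'   accessibility log2 fold-change and the affected group (default EC).
#' @param n_background_peaks background ATAC peaks placed uniformly.
#' @param peak_width_meanlog,peak_width_sdlog log-normal background peak
#'   widths (median 400 bp by default).
#' @param peak_fold Poisson rate multiplier inside any peak relative to
#'   flanking background.
#' @param atac_background_rate expected reads per 100-bp background bin.
#' @param atac_depth per-sample depth factor for ATAC tracks (scalar or
#'   named vector; default 1).
#' @return list of class `design_spec`.
#' @export
design_spec <- function(n_samples,
                        cluster_labels = NULL,
                        de = NULL,
                        dispersion = 0.1,
                        library_sizes = 1,
                        base_mean_range = c(20, 200),
                        kznf_pairs = NULL,
                        accessible_te = NULL,
                        n_background_peaks = 200,
                        peak_width_meanlog = log(400),
                        peak_width_sdlog = 0.25,
                        peak_fold = 4,
                        atac_background_rate = 2,
                        atac_depth = 1) {
  if (is.null(names(n_samples)))
    stop("n_samples must be named by group", call. = FALSE)
  if (!all(names(n_samples) %in% c("EC", "HC", "VP", "ART")))
    stop("groups must be among EC, HC, VP, ART", call. = FALSE)
  if (any(n_samples < 1)) stop("n_samples must be >= 1", call. = FALSE)
  samples <- data.frame(
    sample_id = unlist(lapply(names(n_samples), function(g)
      sprintf("%s_%03d", g, seq_len(n_samples[[g]])))),
    group = rep(names(n_samples), n_samples))
  samples$cluster <- NA_integer_
  if (!is.null(cluster_labels)) {
    if (is.null(names(cluster_labels))) {
      if (length(cluster_labels) != nrow(samples))
        stop("unnamed cluster_labels must cover all samples", call. = FALSE)
      samples$cluster <- as.integer(cluster_labels)
    } else {
      m <- match(samples$sample_id, names(cluster_labels))
      samples$cluster[!is.na(m)] <-
        as.integer(cluster_labels[m[!is.na(m)]])
    }
  }
  if (!is.null(de)) {
    de <- as.data.frame(de)
    if (!all(c("feature_id", "lfc") %in% names(de)))
      stop("de needs feature_id and lfc columns", call. = FALSE)
    if (!any(c("group", "cluster") %in% names(de)))
      stop("de needs a group or cluster column", call. = FALSE)
    if (is.null(de$group)) de$group <- NA_character_
    if (is.null(de$cluster)) de$cluster <- NA_integer_
    if (any(!is.finite(de$lfc)))
      stop("planted fold-changes must be finite", call. = FALSE)
  }
  if (any(dispersion <= 0)) stop("dispersion must be > 0", call. = FALSE)
  if (!is.null(kznf_pairs)) {
    kznf_pairs <- as.data.frame(kznf_pairs)
    if (!all(c("kznf_id", "family", "rho") %in% names(kznf_pairs)))
      stop("kznf_pairs needs kznf_id, family, rho", call. = FALSE)
    kznf_pairs$rho <- abs(kznf_pairs$rho)
    if (any(kznf_pairs$rho <= 0 | kznf_pairs$rho >= 1))
      stop("target |rho| must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(accessible_te)) {
    accessible_te <- as.data.frame(accessible_te)
    if (!all(c("locus_id", "gene_id", "lfc") %in% names(accessible_te)))
      stop("accessible_te needs locus_id, gene_id, lfc", call. = FALSE)
    if (is.null(accessible_te$group)) accessible_te$group <- "EC"
    if (any(!is.finite(accessible_te$lfc)))
      stop("planted fold-changes must be finite", call. = FALSE)
  }
  structure(list(n_samples = n_samples, samples = samples, de = de,
                 dispersion = dispersion, library_sizes = library_sizes,
                 base_mean_range = base_mean_range,
                 kznf_pairs = kznf_pairs, accessible_te = accessible_te,
                 n_background_peaks = n_background_peaks,
                 peak_width_meanlog = peak_width_meanlog,
                 peak_width_sdlog = peak_width_sdlog,
                 peak_fold = peak_fold,
                 atac_background_rate = atac_background_rate,
                 atac_depth = atac_depth),
            class = "design_spec")
}

# uniform placement of n non-overlapping intervals of width w on the
# genome; rejection by rounds, error when the genome is too crowded
.place_nonoverlapping <- function(chrom_sizes, n, width, max_rounds = 100) {
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  avail <- pmax(chrom_sizes - width, 0)
  if (all(avail <= 0))
    stop("locus length exceeds every chromosome", call. = FALSE)
  for (round in seq_len(max_rounds)) {
    need <- n - nrow(placed)
    if (need == 0) break
    chr <- sample(names(chrom_sizes), need * 2, replace = TRUE,
                  prob = avail / sum(avail))
    start <- floor(runif(need * 2) * avail[chr])
    cand <- rbind(placed,
                  data.frame(chrom = chr, start = start,
                             end = start + width))
    cand <- cand[order(cand$chrom, cand$start), ]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))[-1]) {
      if (cand$chrom[i] == cand$chrom[i - 1] &&
          cand$start[i] < cand$end[i - 1]) keep[i] <- FALSE
      else if (!keep[i - 1] && i > 2 &&
               cand$chrom[i] == cand$chrom[i - 2] &&
               cand$start[i] < cand$end[i - 2]) keep[i] <- FALSE
    }
    placed <- cand[keep, ]
    if (nrow(placed) >= n) { placed <- placed[seq_len(n), ]; break }
  }
  if (nrow(placed) < n)
    stop("could not place loci without overlap; use a larger genome",
         call. = FALSE)
  rownames(placed) <- NULL
  placed[sample.int(nrow(placed)), ]  # shuffle away the positional sort
}

#' Generate a synthetic genome annotation
#'
#' Places TE loci (non-overlapping within each family, uniform placement
#' with rejection) and gene TSSs on a toy genome, emulating the structure
#' of a RepeatMasker + gene-annotation pair.  Deterministic for a fixed
#' seed.
#'
#' @param n_chroms number of chromosomes (named `chr1..`).
#' @param chrom_len length of each chromosome (bp; scalar or vector).
#' @param families named list, family -> `list(n_subfamilies, n_loci,
#'   locus_len)`; loci are split evenly over the subfamilies
#'   (`<family>_s<i>` names).
#' @param n_genes number of genes; IDs `gene_0001..`.
#' @param n_kznf how many of the genes are KZNFs (IDs `ZNF_001..`).
#' @param seed RNG seed.
#' @return A [genome_annotation()].
#' @export
make_genome <- function(n_chroms = 1, chrom_len = 1e6, families = list(),
                        n_genes = 0, n_kznf = 0, seed = 1) {
  chrom_sizes <- setNames(rep_len(chrom_len, n_chroms),
                          paste0("chr", seq_len(n_chroms)))
  placed_bases <- sum(vapply(families, function(f)
    f$n_loci * f$locus_len, 0))
  if (placed_bases >= 0.5 * sum(chrom_sizes))
    stop("total TE bases must stay below half the genome; ",
         "use a larger genome", call. = FALSE)
  with_seed(seed, {
    te <- empty_te_loci()
    for (fam in names(families)) {
      f <- families[[fam]]
      pos <- .place_nonoverlapping(chrom_sizes, f$n_loci, f$locus_len)
      sub <- sprintf("%s_s%d", fam,
                     rep_len(seq_len(f$n_subfamilies), f$n_loci))
      te <- rbind(te, data.frame(
        locus_id = sprintf("%s.%d", sub,
                           stats::ave(seq_len(f$n_loci), sub,
                                      FUN = seq_along)),
        chrom = pos$chrom, start = pos$start, end = pos$end,
        strand = sample(c("+", "-"), f$n_loci, replace = TRUE),
        subfamily = sub, family = fam))
    }
    genes <- empty_genes()
    if (n_genes > 0) {
      chr <- sample(names(chrom_sizes), n_genes, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
      tss <- floor(runif(n_genes) * chrom_sizes[chr])
      is_kznf <- seq_len(n_genes) > n_genes - n_kznf
      ids <- ifelse(is_kznf,
                    sprintf("ZNF_%03d", cumsum(is_kznf)),
                    sprintf("gene_%04d", seq_len(n_genes)))
      genes <- data.frame(gene_id = ids, chrom = chr, tss = as.numeric(tss),
                          strand = sample(c("+", "-"), n_genes,
                                          replace = TRUE),
                          class = ifelse(is_kznf, "kznf", "gene"))
    }
    genome_annotation(chrom_sizes, te, genes)
  })
}

#' Plant proximal TE-gene links in an annotation
#'
#' Selects `n_links` TE loci that have a gene TSS within `max_dist` and
#' pairs each with its nearest such gene (one gene per link), for use as
#' the `accessible_te` slot of a [design_spec()].
#'
#' @param annotation a [genome_annotation()].
#' @param n_links number of links to plant.
#' @param lfc accessibility log2 fold-change planted in `group`.
#' @param max_dist maximum TSS distance (bp).
#' @param group affected group.
#' @param seed RNG seed.
#' @return data.frame `locus_id, gene_id, lfc, group`.
#' @export
plant_cisreg_links <- function(annotation, n_links, lfc = 2,
                               max_dist = 10000, group = "EC", seed = 1) {
  te <- annotation$te_loci
  genes <- annotation$genes[annotation$genes$class == "gene", ]
  with_seed(seed, {
    ord <- sample.int(nrow(te))
    used_genes <- character()
    links <- list()
    for (i in ord) {
      if (length(links) == n_links) break
      g <- genes[genes$chrom == te$chrom[i] &
                   !(genes$gene_id %in% used_genes), ]
      if (!nrow(g)) next
      d <- ifelse(g$tss >= te$start[i] & g$tss < te$end[i], 0,
                  ifelse(g$tss >= te$end[i], g$tss - te$end[i],
                         te$start[i] - g$tss))
      j <- which.min(d)
      if (d[j] > max_dist) next
      used_genes <- c(used_genes, g$gene_id[j])
      links[[length(links) + 1L]] <-
        data.frame(locus_id = te$locus_id[i], gene_id = g$gene_id[j],
                   lfc = lfc, group = group)
    }
    if (length(links) < n_links)
      stop("could not find enough TE loci with a gene TSS within ",
           max_dist, " bp", call. = FALSE)
    do.call(rbind, links)
  })
}

.per_sample <- function(x, sample_ids, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(setNames(rep(x, length(sample_ids)), sample_ids))
  if (is.null(names(x)) && length(x) == length(sample_ids))
    return(setNames(x, sample_ids))
  out <- x[sample_ids]
  if (anyNA(out)) stop("missing ", what, " for some samples", call. = FALSE)
  out
}

#' Simulate gene + TE-locus counts with planted structure
#'
#' Draws `counts[f, s] ~ NegBin(mean = base_f * libsize_s * 2^lfc(f, s),
#' dispersion_f)` where the fold-change applies when sample `s` belongs to
#' the group or planted cluster named for feature `f` in the design.
#' Planted KZNF-TE couplings are realized via a standard-normal
#' per-sample latent factor `z`: the KZNF mean is multiplied by
#' `exp(lambda z)` and every locus mean of the target family by
#' `exp(-lambda z)`, with `lambda = sqrt(dispersion * rho / (1 - rho))`
#' chosen so the log-scale correlation approximates the target `rho`
#' against the NB noise floor.
#'
#' @param annotation a [genome_annotation()]; features are its genes plus
#'   TE loci.  Genes get a nominal length of 1000 bp in the feature
#'   metadata; TE loci their annotated length.
#' @param design a [design_spec()].
#' @param seed RNG seed.
#' @return list with `counts` (an `abundance_matrix` of raw counts) and
#'   `truth` (a `truth_table` echoing the planted quantities plus
#'   realized group means).
#' @export
simulate_counts <- function(annotation, design, seed = 1) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(design, "design_spec"))
  genes <- annotation$genes
  te <- annotation$te_loci
  feats <- c(genes$gene_id, te$locus_id)
  if (!length(feats)) stop("annotation has no features", call. = FALSE)
  meta <- data.frame(
    feature_id = feats,
    kind = c(rep("gene", nrow(genes)), rep("te_locus", nrow(te))),
    length = c(rep(1000, nrow(genes)), te$end - te$start),
    family = c(rep(NA_character_, nrow(genes)), te$family),
    class = c(genes$class, rep(NA_character_, nrow(te))))
  samples <- design$samples
  if (!is.null(design$de)) {
    missing <- setdiff(design$de$feature_id, feats)
    if (length(missing))
      stop("planted DE feature not in annotation: ", missing[1],
           call. = FALSE)
  }
  if (!is.null(design$kznf_pairs)) {
    if (!all(design$kznf_pairs$kznf_id %in% genes$gene_id))
      stop("planted KZNF not in annotation", call. = FALSE)
    if (!all(design$kznf_pairs$family %in% te$family))
      stop("planted TE family not in annotation", call. = FALSE)
  }
  disp <- if (length(design$dispersion) == 1L)
    setNames(rep(design$dispersion, length(feats)), feats)
  else {
    d <- design$dispersion[feats]
    if (anyNA(d)) stop("missing dispersion for some features", call. = FALSE)
    d
  }
  lib <- .per_sample(design$library_sizes, samples$sample_id,
                     "library size")
  with_seed(seed, {
    base <- 2^runif(length(feats), log2(design$base_mean_range[1]),
                    log2(design$base_mean_range[2]))
    names(base) <- feats
    mu <- outer(base, lib)
    dimnames(mu) <- list(feats, samples$sample_id)
    if (!is.null(design$de)) {
      for (r in seq_len(nrow(design$de))) {
        f <- design$de$feature_id[r]
        affected <- if (!is.na(design$de$group[r]))
          samples$group == design$de$group[r]
        else samples$cluster %in% design$de$cluster[r]
        mu[f, affected] <- mu[f, affected] * 2^design$de$lfc[r]
      }
    }
    latent <- NULL
    if (!is.null(design$kznf_pairs)) {
      kp <- design$kznf_pairs
      # latent-factor strength targeting |rho| on the log scale against
      # the NB noise floor: the KZNF sees dispersion alpha, the family
      # mean of n loci about alpha/n; solve
      # rho^2 (l^2 + a_k)(l^2 + a_f) = l^4 for l^2
      alpha_k <- mean(disp)
      n_fam <- table(te$family)
      kp$lambda <- vapply(seq_len(nrow(kp)), function(r) {
        a_f <- alpha_k / max(1, n_fam[[kp$family[r]]])
        r2 <- kp$rho[r]^2
        x <- (r2 * (alpha_k + a_f) +
                sqrt(r2^2 * (alpha_k + a_f)^2 +
                       4 * (1 - r2) * r2 * alpha_k * a_f)) /
          (2 * (1 - r2))
        sqrt(x)
      }, 0)
      latent <- matrix(rnorm(nrow(kp) * nrow(samples)), nrow(kp),
                       dimnames = list(NULL, samples$sample_id))
      for (r in seq_len(nrow(kp))) {
        z <- latent[r, ]
        mu[kp$kznf_id[r], ] <- mu[kp$kznf_id[r], ] * exp(kp$lambda[r] * z)
        fam_loci <- te$locus_id[te$family == kp$family[r]]
        mu[fam_loci, ] <- mu[fam_loci, ] *
          rep(exp(-kp$lambda[r] * z), each = length(fam_loci))
      }
      design$kznf_pairs <- kp
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = rep(1 / disp,
                                                             ncol(mu))),
                     nrow(mu), dimnames = dimnames(mu))
    group_means <- vapply(unique(samples$group), function(g)
      rowMeans(counts[, samples$group == g, drop = FALSE]),
      numeric(nrow(counts)))
    truth <- structure(list(samples = samples, de = design$de,
                            kznf_pairs = design$kznf_pairs,
                            library_sizes = lib, base_mean = base,
                            group_means = group_means,
                            latent = latent),
                       class = "truth_table")
    list(counts = abundance_matrix(counts, "counts", meta), truth = truth)
  })
}

#' Simulate ambiguous read classes
#'
#' Draws `n_reads` source features from `true_props`, then assigns each
#' read to one of the ambiguity classes containing its source feature
#' (uniformly, or proportionally to `class_weights`).  When the classes
#' partition the features the class of a read is simply the class holding
#' its source, as in equivalence-class quantification.
#'
#' @param true_props named vector of true feature proportions (sums to 1).
#' @param classes named list, class -> character vector of member
#'   features; every feature must appear in at least one class.
#' @param n_reads total reads.
#' @param seed RNG seed.
#' @param class_weights optional named vector of per-class weights biasing
#'   which containing class a read reports.
#' @return list of elements `list(features, count)` (one per input class,
#'   counts summing to `n_reads`), suitable for [em_quantify()].
#' @export
simulate_read_classes <- function(true_props, classes, n_reads, seed = 1,
                                  class_weights = NULL) {
  stopifnot(abs(sum(true_props) - 1) < 1e-8, !is.null(names(true_props)))
  feats <- names(true_props)
  if (is.null(names(classes)))
    names(classes) <- sprintf("class_%d", seq_along(classes))
  membership <- lapply(feats, function(f)
    which(vapply(classes, function(cl) f %in% cl, TRUE)))
  names(membership) <- feats
  orphan <- feats[lengths(membership) == 0]
  if (length(orphan))
    stop("feature absent from all classes: ", orphan[1], call. = FALSE)
  w <- if (is.null(class_weights)) setNames(rep(1, length(classes)),
                                            names(classes))
       else class_weights[names(classes)]
  if (anyNA(w)) stop("class_weights missing for some classes", call. = FALSE)
  with_seed(seed, {
    src <- as.vector(rmultinom(1, n_reads, true_props))
    class_counts <- setNames(numeric(length(classes)), names(classes))
    for (i in seq_along(feats)) {
      if (src[i] == 0) next
      ks <- membership[[i]]
      if (length(ks) == 1L) {
        class_counts[ks] <- class_counts[ks] + src[i]
      } else {
        add <- as.vector(rmultinom(1, src[i], w[ks]))
        class_counts[ks] <- class_counts[ks] + add
      }
    }
    lapply(names(classes), function(k)
      list(features = classes[[k]], count = unname(class_counts[k])))
  })
}

#' Simulate group peak sets and per-sample accessibility tracks
#'
#' Background peaks are placed uniformly over the genome with log-normal
#' widths; planted peaks are centered on the design's accessible TE loci
#' with their summit inside the TE.  Per-sample signal is Poisson per
#' 100-bp bin: background rate everywhere, `peak_fold`-elevated inside
#' any peak, and additionally `2^lfc`-elevated inside planted peaks for
#' samples of the planted group, all scaled by the per-sample depth
#' factor.
#'
#' @param annotation a [genome_annotation()].
#' @param design a [design_spec()] (uses `accessible_te`,
#'   `n_background_peaks`, peak-width, rate and depth settings).
#' @param seed RNG seed.
#' @param bin_size track bin width (bp, default 100).
#' @return list with `peaks` (named list group -> [peak_set()]), `tracks`
#'   (named list sample -> raw [signal_track()]) and `truth`
#'   (`truth_table` echoing planted loci, their peak IDs and background
#'   peak IDs).
#' @export
simulate_atac <- function(annotation, design, seed = 1, bin_size = 100) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(design, "design_spec"))
  chrom_sizes <- annotation$chrom_sizes
  te <- annotation$te_loci
  genes <- annotation$genes
  planted <- design$accessible_te
  if (!is.null(planted)) {
    missing <- setdiff(planted$locus_id, te$locus_id)
    if (length(missing))
      stop("planted TE locus not in annotation: ", missing[1],
           call. = FALSE)
    missing <- setdiff(planted$gene_id, genes$gene_id)
    if (length(missing))
      stop("planted linked gene not in annotation: ", missing[1],
           call. = FALSE)
    for (r in seq_len(nrow(planted))) {
      ti <- te[te$locus_id == planted$locus_id[r], ]
      gi <- genes[genes$gene_id == planted$gene_id[r], ]
      d <- if (gi$chrom != ti$chrom) Inf
           else if (gi$tss >= ti$start && gi$tss < ti$end) 0
           else if (gi$tss >= ti$end) gi$tss - ti$end
           else ti$start - gi$tss
      if (d > 10000)
        stop("planted link ", planted$locus_id[r], " -> ",
             planted$gene_id[r], " exceeds 10 kb", call. = FALSE)
    }
  }
  samples <- design$samples
  depth <- .per_sample(design$atac_depth, samples$sample_id, "atac depth")
  with_seed(seed, {
    nbg <- design$n_background_peaks
    widths <- pmax(round(rlnorm(nbg, design$peak_width_meanlog,
                                design$peak_width_sdlog)), 50)
    avail <- vapply(widths, function(w)
      sum(pmax(chrom_sizes - w, 0)), 0)
    if (any(avail <= 0))
      stop("background peak wider than every chromosome", call. = FALSE)
    chr <- vapply(widths, function(w) {
      a <- pmax(chrom_sizes - w, 0)
      sample(names(chrom_sizes), 1, prob = a / sum(a))
    }, "")
    start <- floor(runif(nbg) * (chrom_sizes[chr] - widths))
    bg <- data.frame(peak_id = sprintf("bg_peak_%04d", seq_len(nbg)),
                     chrom = chr, start = start, end = start + widths,
                     summit_offset = floor(widths / 2), score = 100)
    planted_peaks <- NULL
    if (!is.null(planted) && nrow(planted)) {
      ti <- te[match(planted$locus_id, te$locus_id), ]
      pad <- 100
      pstart <- pmax(ti$start - pad, 0)
      pend <- pmin(ti$end + pad, chrom_sizes[ti$chrom])
      mid <- floor((ti$start + ti$end) / 2)  # summit at TE center
      planted_peaks <- data.frame(
        peak_id = sprintf("planted_peak_%04d", seq_len(nrow(planted))),
        chrom = ti$chrom, start = pstart, end = pend,
        summit_offset = mid - pstart, score = 500)
    }
    groups <- names(design$n_samples)
    peaks <- lapply(groups, function(g) {
      df <- bg
      if (!is.null(planted_peaks) && any(planted$group == g))
        df <- rbind(df, planted_peaks[planted$group == g, ])
      peak_set(df, sample_or_group = g)
    })
    names(peaks) <- groups
    # per-bin Poisson rates shared within a group
    base_rate <- lapply(names(chrom_sizes), function(chrn)
      rep(design$atac_background_rate,
          ceiling(chrom_sizes[[chrn]] / bin_size)))
    names(base_rate) <- names(chrom_sizes)
    mark_bins <- function(rate, df, mult) {
      for (i in seq_len(nrow(df))) {
        b_lo <- floor(df$start[i] / bin_size) + 1
        b_hi <- ceiling(df$end[i] / bin_size)
        rate[[df$chrom[i]]][b_lo:b_hi] <-
          rate[[df$chrom[i]]][b_lo:b_hi] * mult
      }
      rate
    }
    rate_bg <- mark_bins(base_rate, bg, design$peak_fold)
    group_rate <- lapply(groups, function(g) {
      r <- rate_bg
      if (!is.null(planted_peaks)) {
        r <- mark_bins(r, planted_peaks, design$peak_fold)
        boost <- planted$group == g
        if (any(boost)) {
          for (i in which(boost)) {
            df <- planted_peaks[i, ]
            r <- mark_bins(r, df, 2^planted$lfc[i])
          }
        }
      }
      r
    })
    names(group_rate) <- groups
    tracks <- lapply(seq_len(nrow(samples)), function(si) {
      g <- samples$group[si]
      dep <- depth[[samples$sample_id[si]]]
      vals <- lapply(group_rate[[g]], function(r)
        rpois(length(r), r * dep))
      names(vals) <- names(chrom_sizes)
      signal_track(vals, bin_size, chrom_sizes, "raw")
    })
    names(tracks) <- samples$sample_id
    truth <- structure(list(samples = samples,
                            accessible_te = if (is.null(planted)) NULL
                              else cbind(planted,
                                         peak_id = planted_peaks$peak_id),
                            background_peaks = bg$peak_id,
                            depth = depth),
                       class = "truth_table")
    list(peaks = peaks, tracks = tracks, truth = truth)
  })
}
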