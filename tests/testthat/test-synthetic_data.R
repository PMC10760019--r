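# Generators: determinism, conservation, and planted-effect realization.

test_that("make_genome places loci within bounds, non-overlapping per family", {
  g <- make_genome(1, 1e6,
                   families = lapply(setNames(1:3, paste0("F", 1:3)),
                                     function(i) list(n_subfamilies = 1,
                                                      n_loci = 100,
                                                      locus_len = 500)),
                   seed = 7)
  te <- g$te_loci
  expect_equal(nrow(te), 300L)
  expect_true(all(te$start >= 0 & te$end <= 1e6))
  for (fam in unique(te$family)) {
    x <- te[te$family == fam, ]
    x <- x[order(x$start), ]
    expect_true(all(diff(x$start) >= (x$end - x$start)[-nrow(x)]))
  }
})

test_that("make_genome with no TE spec gives an empty locus table", {
  g <- make_genome(1, 1e5, n_genes = 10, seed = 1)
  expect_equal(nrow(g$te_loci), 0L)
  expect_equal(nrow(g$genes), 10L)
})

test_that("make_genome is deterministic and rejects crowded genomes", {
  fam <- list(F1 = list(n_subfamilies = 2, n_loci = 40, locus_len = 300))
  g1 <- make_genome(2, 5e5, fam, n_genes = 20, n_kznf = 3, seed = 11)
  g2 <- make_genome(2, 5e5, fam, n_genes = 20, n_kznf = 3, seed = 11)
  expect_identical(g1$te_loci, g2$te_loci)
  expect_identical(g1$genes, g2$genes)
  expect_error(
    make_genome(1, 1e4,
                families = list(F1 = list(n_subfamilies = 1, n_loci = 100,
                                          locus_len = 100))),
    "larger genome")
})

test_that("library size scaling doubles a sample's column sum", {
  g <- make_genome(1, 1e6, n_genes = 300, seed = 2)
  base <- design_spec(c(EC = 4, HC = 4))
  lib <- setNames(rep(1, 8), base$samples$sample_id)
  lib["EC_001"] <- 2
  d <- design_spec(c(EC = 4, HC = 4), library_sizes = lib)
  cs <- sapply(1:5, function(s) {
    m <- as.matrix(simulate_counts(g, d, seed = s)$counts)
    m2 <- as.matrix(simulate_counts(g, base, seed = s)$counts)
    sum(m[, "EC_001"]) / mean(colSums(m[, -1])) /
      (sum(m2[, "EC_001"]) / mean(colSums(m2[, -1])))
  })
  expect_equal(mean(cs), 2, tolerance = 0.1)
})

test_that("planted fold change is realized on the TPM scale", {
  # lfc = 2 at n = 20/group, dispersion 0.1: EC/HC mean-TPM ratio close
  # to 4 (compositional shift from one planted feature is negligible)
  g <- make_genome(1, 1e6, n_genes = 400, seed = 3)
  d <- design_spec(c(EC = 20, HC = 20),
                   de = data.frame(feature_id = "gene_0001", lfc = 2,
                                   group = "EC"))
  ratios <- sapply(1:10, function(s) {
    sim <- simulate_counts(g, d, seed = s)
    tpm <- as.matrix(tpm_normalize(sim$counts))
    grp <- sim$truth$samples$group
    mean(tpm["gene_0001", grp == "EC"]) /
      mean(tpm["gene_0001", grp == "HC"])
  })
  expect_gt(mean(ratios), 3.4)
  expect_lt(mean(ratios), 4.7)
})

test_that("planted effects are recoverable from realized group means", {
  g <- make_genome(1, 1e6, n_genes = 200, seed = 4)
  d <- design_spec(c(EC = 50, HC = 50),
                   de = data.frame(feature_id = c("gene_0001", "gene_0002"),
                                   lfc = c(2, -1.5), group = "EC"))
  sim <- simulate_counts(g, d, seed = 9)
  gm <- sim$truth$group_means
  est <- log2(gm[c("gene_0001", "gene_0002"), "EC"] /
                gm[c("gene_0001", "gene_0002"), "HC"])
  expect_equal(unname(est), c(2, -1.5), tolerance = 0.3)
})

test_that("read class simulation conserves reads and honors ambiguity", {
  props <- c(A = 0.7, B = 0.3)
  # fully unique classes: counts are a plain multinomial draw
  cls <- simulate_read_classes(props, list(cA = "A", cB = "B"), 10000,
                               seed = 5)
  counts <- vapply(cls, `[[`, 0, "count")
  expect_equal(sum(counts), 10000)
  expect_equal(counts[1] / 10000, 0.7, tolerance = 0.05)
  # single shared class captures everything
  cls2 <- simulate_read_classes(props, list(shared = c("A", "B")), 5000,
                                seed = 6)
  expect_equal(cls2[[1]]$count, 5000)
  expect_error(
    simulate_read_classes(c(A = 0.5, B = 0.5), list(cA = "A"), 10),
    "absent from all classes")
})

test_that("read class simulation is deterministic given the seed", {
  props <- setNames(rep(0.1, 10), paste0("f", 1:10))
  classes <- c(as.list(setNames(paste0("f", 1:10), paste0("s", 1:10))),
               list(amb1 = c("f1", "f2"), amb2 = c("f3", "f4")))
  a <- simulate_read_classes(props, classes, 1000, seed = 3,
                             class_weights = setNames(c(rep(1, 10), 0.25,
                                                        0.25),
                                                      names(classes)))
  b <- simulate_read_classes(props, classes, 1000, seed = 3,
                             class_weights = setNames(c(rep(1, 10), 0.25,
                                                        0.25),
                                                      names(classes)))
  expect_identical(a, b)
  expect_equal(sum(vapply(a, `[[`, 0, "count")), 1000)
})

test_that("simulated ATAC respects depth and planted accessibility", {
  g <- make_genome(1, 5e5,
                   families = list(F1 = list(n_subfamilies = 1,
                                             n_loci = 30,
                                             locus_len = 400)),
                   n_genes = 200, seed = 8)
  links <- plant_cisreg_links(g, 3, lfc = 2, seed = 2)
  depth <- setNames(c(1, 0, 1, 1), c("EC_001", "EC_002", "HC_001",
                                     "HC_002"))
  d <- design_spec(c(EC = 2, HC = 2), accessible_te = links,
                   n_background_peaks = 30, atac_depth = depth)
  atac <- simulate_atac(g, d, seed = 10)
  expect_true(all(unlist(atac$tracks$EC_002$values) == 0))
  # planted loci more accessible in EC than HC in most seeds
  hits <- sapply(1:10, function(s) {
    a <- simulate_atac(g, design_spec(c(EC = 2, HC = 2),
                                      accessible_te = links,
                                      n_background_peaks = 30), seed = s)
    te <- g$te_loci[match(links$locus_id, g$te_loci$locus_id), ]
    ec <- rowMeans(sapply(c("EC_001", "EC_002"), function(sm)
      sapply(seq_len(nrow(te)), function(i) {
        b <- (floor(te$start[i] / 100) + 1):ceiling(te$end[i] / 100)
        mean(a$tracks[[sm]]$values[[te$chrom[i]]][b])
      })))
    hc <- rowMeans(sapply(c("HC_001", "HC_002"), function(sm)
      sapply(seq_len(nrow(te)), function(i) {
        b <- (floor(te$start[i] / 100) + 1):ceiling(te$end[i] / 100)
        mean(a$tracks[[sm]]$values[[te$chrom[i]]][b])
      })))
    all(ec > hc)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("without planted loci, summit-in-TE rate matches TE bp fraction", {
  g <- make_genome(1, 1e6,
                   families = list(F1 = list(n_subfamilies = 1,
                                             n_loci = 300,
                                             locus_len = 500)),
                   seed = 12)
  te_frac <- sum(g$te_loci$end - g$te_loci$start) / 1e6
  pk <- uniform_peaks(13, 2000, 200, 1e6)
  ov <- peak_te_overlap(pk, g, min_frac = 0, require_summit = TRUE)
  rate <- length(unique(ov$peak_id)) / nrow(pk)
  expect_equal(rate, te_frac, tolerance = 0.15)
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_genome(1, 1e5, n_genes = 5, seed = 42))
  expect_identical(runif(1), before)
})
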