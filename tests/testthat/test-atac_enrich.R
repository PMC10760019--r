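# Track normalization, peak-TE overlap, matched-null enrichment,
# metaprofiles and per-cluster accessibility.

test_that("RPKM follows its definition and is depth-invariant", {
  cs <- c(chr1 = 1000)
  v <- c(10, rep(0, 9))
  tr <- signal_track(list(chr1 = v), 100, cs,
                     total_reads = 1e6)
  rk <- rpkm_bins(tr)
  expect_equal(rk$values$chr1[1], 100)  # 10 / (0.1 kb * 1 M reads)
  # doubling all bins (and hence depth) leaves RPKM unchanged
  tr2 <- signal_track(list(chr1 = v * 2), 100, cs, total_reads = 2e6)
  expect_equal(rpkm_bins(tr2)$values, rk$values)
  expect_error(rpkm_bins(tr, bin = 50), "bin mismatch")
})

test_that("z-scoring a uniform track yields all zeros", {
  cs <- c(chr1 = 500)
  tr <- signal_track(list(chr1 = rep(4, 5)), 100, cs)
  expect_true(all(zscore_track(tr)$values$chr1 == 0))
  tr2 <- signal_track(list(chr1 = c(1, 2, 3, 4, 5)), 100, cs)
  z <- unlist(zscore_track(tr2)$values)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("peak-TE overlap honors the 50% and summit rules at boundaries", {
  te <- data.frame(locus_id = c("t1", "t2"), chrom = "chr1",
                   start = c(0, 550), end = c(350, 1000),
                   strand = "+", subfamily = "S", family = "F")
  # peak 100..600 summit at 250 (inside t1): overlap with t1 = 250,
  # frac exactly 0.5 -> retained; overlap with t2 = 50, frac 0.1 -> dropped
  pk <- peak_set(data.frame(peak_id = "p1", chrom = "chr1", start = 100,
                            end = 600, summit_offset = 150))
  ov <- peak_te_overlap(pk, te)
  expect_equal(ov$locus_id, "t1")
  expect_equal(ov$overlap_frac_of_peak, 0.5)
  expect_true(ov$summit_in_te)
  # summit outside the TE drops the pair when required
  pk2 <- peak_set(data.frame(peak_id = "p1", chrom = "chr1", start = 100,
                             end = 600, summit_offset = 450))
  expect_equal(nrow(peak_te_overlap(pk2, te)), 0L)
  expect_equal(peak_te_overlap(pk2, te, require_summit = FALSE)$locus_id,
               "t1")
})

test_that("overlap table matches the brute-force all-pairs scan", {
  with_seed(22, {
    n <- 200
    ps <- floor(runif(n) * 9500)
    pk <- peak_set(data.frame(peak_id = sprintf("p%d", 1:n), chrom = "chr1",
                              start = ps, end = ps + sample(100:400, n, TRUE)))
    ts <- floor(runif(150) * 9500)
    te <- data.frame(locus_id = sprintf("t%d", 1:150), chrom = "chr1",
                     start = ts, end = ts + sample(100:500, 150, TRUE),
                     strand = "+", subfamily = "S", family = "F")
  })
  got <- peak_te_overlap(pk, te)
  want <- brute_overlap(pk, te)
  key <- function(d) sort(paste(d$peak_id, d$locus_id))
  expect_identical(key(got), key(want))
  m <- match(paste(want$peak_id, want$locus_id),
             paste(got$peak_id, got$locus_id))
  expect_equal(got$overlap_bp[m], want$overlap_bp)
})

test_that("overlap is invariant under translation and chrom renaming", {
  with_seed(23, {
    ps <- floor(runif(50) * 5000)
    pk <- peak_set(data.frame(peak_id = sprintf("p%d", 1:50),
                              chrom = "chrA", start = ps, end = ps + 200))
    ts <- floor(runif(50) * 5000)
    te <- data.frame(locus_id = sprintf("t%d", 1:50), chrom = "chrA",
                     start = ts, end = ts + 300, strand = "+",
                     subfamily = "S", family = "F")
  })
  ov1 <- peak_te_overlap(pk, te)
  pk2 <- pk; te2 <- te
  pk2$start <- pk$start + 7777; pk2$end <- pk$end + 7777
  te2$start <- te$start + 7777; te2$end <- te$end + 7777
  pk2$chrom <- te2$chrom <- "chrB"
  ov2 <- peak_te_overlap(pk2, te2)
  expect_equal(ov1$peak_id, ov2$peak_id)
  expect_equal(ov1$overlap_bp, ov2$overlap_bp)
})

test_that("degenerate random draws give zero enrichment", {
  # one chromosome exactly as wide as the single peak: every random draw
  # reproduces the observed placement
  g <- genome_annotation(c(chr1 = 500),
                         te_loci = data.frame(locus_id = "t1",
                                              chrom = "chr1", start = 100,
                                              end = 400, strand = "+",
                                              subfamily = "S",
                                              family = "F"))
  pk <- peak_set(data.frame(peak_id = "p1", chrom = "chr1", start = 0,
                            end = 500, summit_offset = 250))
  enr <- family_enrichment(pk, g, n_draws = 1, seed = 1)
  expect_equal(enr$log2_ratio, 0)
  expect_equal(enr$p_enrich, 1)
})

test_that("planted peak concentration on a family is detected", {
  g <- make_genome(1, 2e6,
                   families = list(TARGET = list(n_subfamilies = 1,
                                                 n_loci = 60,
                                                 locus_len = 400),
                                   OTHER = list(n_subfamilies = 1,
                                                n_loci = 60,
                                                locus_len = 400)),
                   seed = 24)
  te <- g$te_loci[g$te_loci$family == "TARGET", ][1:50, ]
  planted <- peak_set(data.frame(
    peak_id = sprintf("pl%d", 1:50), chrom = te$chrom,
    start = te$start - 20, end = te$end + 20,
    summit_offset = floor((te$end - te$start) / 2) + 20))
  pk <- rbind(uniform_peaks(25, 50, 300, 2e6), planted)
  class(pk) <- c("peak_set", "data.frame")
  enr <- family_enrichment(pk, g, n_draws = 99, seed = 26)
  row <- enr[enr$family == "TARGET", ]
  expect_gte(row$log2_ratio, 1.5)
  expect_equal(row$p_enrich, 1 / 100)
})

test_that("peak wider than every chromosome errors", {
  g <- genome_annotation(c(chr1 = 500))
  wide <- peak_set(data.frame(peak_id = "p1", chrom = "chr1", start = 0,
                              end = 501))
  expect_error(family_enrichment(wide, g, n_draws = 2, seed = 1),
               "wider than every chromosome")
})

test_that("metaprofile matches brute-force window extraction", {
  cs <- c(chr1 = 20000)
  v <- with_seed(27, rpois(200, 5))
  tr <- signal_track(list(chr1 = v), 100, cs)
  loci <- data.frame(locus_id = c("a", "b", "c"), chrom = "chr1",
                     start = c(5000, 9130, 17040), end = c(5400, 9530, 17440),
                     strand = c("+", "-", "+"), subfamily = "S",
                     family = "F")
  prof <- metaprofile(list(g1 = tr), loci, window = 1000, bin = 100)
  expect_equal(ncol(prof), 21)
  rpm <- v * 1e6 / sum(v)
  brute <- sapply(seq(-1000, 1000, 100), function(off) {
    mean(sapply(loci$start, function(s) {
      pos <- s + off
      rpm[floor(pos / 100) + 1]
    }))
  })
  expect_equal(unname(prof[1, ]), brute)
})

test_that("metaprofile peaks at the anchor for spiked signal", {
  cs <- c(chr1 = 50000)
  loci <- data.frame(locus_id = paste0("l", 1:5), chrom = "chr1",
                     start = c(10000, 20000, 30000, 40000, 45000),
                     end = c(10400, 20400, 30400, 40400, 45400),
                     strand = "+", subfamily = "S", family = "F")
  v <- numeric(500)
  v[floor(loci$start / 100) + 1] <- 100
  tr <- signal_track(list(chr1 = v + 1), 100, cs)
  prof <- metaprofile(list(g1 = tr), loci)
  expect_equal(attr(prof, "offsets")[which.max(prof[1, ])], 0)
  # flat track gives a flat profile at the RPM constant
  flat <- signal_track(list(chr1 = rep(2, 500)), 100, cs)
  pf <- metaprofile(list(g1 = flat), loci)
  expect_true(all(abs(pf[1, ] - pf[1, 1]) < 1e-9))
  expect_error(metaprofile(list(g1 = tr), loci[0, ]), "0 loci")
  expect_error(metaprofile(list(g1 = tr), loci, window = 5050), "divisible")
})

test_that("per-cluster family accessibility summarizes sample means", {
  cs <- c(chr1 = 10000)
  loci <- data.frame(locus_id = "l1", chrom = "chr1", start = 1000,
                     end = 1300, strand = "+", subfamily = "S",
                     family = "F")
  mk_track <- function(val) {
    v <- rep(1, 100); v[11:13] <- val
    signal_track(list(chr1 = v), 100, cs, normalization = "RPM",
                 total_reads = 100)
  }
  tracks <- list(s1 = mk_track(10), s2 = mk_track(20), s3 = mk_track(1))
  labels <- setNames(c(1, 1, 2), c("s1", "s2", "s3"))
  acc <- family_accessibility_by_cluster(tracks, loci, labels)
  expect_equal(acc$mean[acc$cluster == 1], 15)
  expect_equal(acc$mean[acc$cluster == 2], 1)  # single-sample cluster
  expect_true(is.na(acc$sd[acc$cluster == 2]))
  # all-equal tracks: identical means
  tracks2 <- list(s1 = mk_track(5), s2 = mk_track(5), s3 = mk_track(5))
  acc2 <- family_accessibility_by_cluster(tracks2, loci, labels)
  expect_equal(acc2$mean[1], acc2$mean[2])
})
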