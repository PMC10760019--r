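# EM quantification, TPM, family aggregation, log/z scaling.

test_that("EM with singleton classes equals the closed-form estimate", {
  fit <- em_quantify(list(list(features = "A", count = 90),
                          list(features = "B", count = 10)),
                     c(A = 1000, B = 1000))
  expect_equal(unname(fit$tpm), c(900000, 100000))
  expect_equal(unname(fit$counts), c(90, 10))
  # length correction: same counts, B twice as long
  fit2 <- em_quantify(list(list(features = "A", count = 10),
                           list(features = "B", count = 10)),
                      c(A = 100, B = 200))
  expect_equal(unname(fit2$tpm), c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
})

test_that("EM resolves ambiguous mass to features with unique support", {
  fit <- em_quantify(list(list(features = "A", count = 50),
                          list(features = "B", count = 0),
                          list(features = c("A", "B"), count = 50)),
                     c(A = 1000, B = 1000), tol = 1e-10)
  expect_equal(unname(fit$counts), c(100, 0), tolerance = 1e-6)
  fit2 <- em_quantify(list(list(features = "A", count = 30),
                           list(features = "B", count = 30),
                           list(features = c("A", "B"), count = 40)),
                      c(A = 1000, B = 1000))
  expect_equal(unname(fit2$counts), c(50, 50), tolerance = 1e-6)
})

test_that("EM likelihood trace is non-decreasing on random instances", {
  for (s in 1:25) {
    inst <- with_seed(s, {
      nf <- sample(3:8, 1)
      feats <- paste0("f", seq_len(nf))
      classes <- lapply(seq_len(sample(4:10, 1)), function(i)
        list(features = sample(feats, sample(1:3, 1)),
             count = rpois(1, 50)))
      # ensure every feature has some class
      classes <- c(classes, lapply(feats, function(f)
        list(features = f, count = rpois(1, 20))))
      list(classes = classes,
           lengths = setNames(sample(200:2000, nf), feats))
    })
    fit <- em_quantify(inst$classes, inst$lengths)
    expect_true(all(diff(fit$loglik) >= -1e-9))
    expect_equal(sum(fit$counts),
                 sum(vapply(inst$classes, `[[`, 0, "count")))
  }
})

test_that("EM validates its inputs", {
  expect_error(em_quantify(list(), c(A = 100)), "empty class set")
  expect_error(em_quantify(list(list(features = "A", count = 1)),
                           c(A = 0)), "> 0")
  expect_error(em_quantify(list(list(features = character(), count = 1)),
                           c(A = 100)), "empty feature set")
})

test_that("TPM normalization matches hand arithmetic and sums to 1e6", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("A", "B"), "s1"))
  tpm <- as.matrix(tpm_normalize(m, c(A = 100, B = 200)))
  expect_equal(unname(tpm[, 1]), c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-6)
  one <- matrix(5, 1, 1, dimnames = list("A", "s1"))
  expect_equal(as.vector(as.matrix(tpm_normalize(one, c(A = 50)))), 1e6)
  rnd <- with_seed(1, matrix(rpois(200, 20), 20,
                             dimnames = list(paste0("f", 1:20),
                                             paste0("s", 1:10))))
  cs <- colSums(as.matrix(tpm_normalize(rnd, setNames(
    rep(500, 20), paste0("f", 1:20)))))
  expect_equal(unname(cs), rep(1e6, 10), tolerance = 1e-6)
})

test_that("all-zero columns yield zero TPM with a warning, not an error", {
  m <- matrix(c(5, 0), 1, 2, dimnames = list("A", c("s1", "s2")))
  expect_warning(tpm <- tpm_normalize(m, c(A = 100)), "all-zero")
  expect_equal(as.vector(as.matrix(tpm)), c(1e6, 0))
})

test_that("family aggregation averages member loci in expression space", {
  m <- matrix(c(2, 4, 6, 1, 3, 5), 3, 2,
              dimnames = list(c("l1", "l2", "l3"), c("s1", "s2")))
  fams <- c(l1 = "FAM", l2 = "FAM", l3 = "FAM")
  agg <- as.matrix(aggregate_families(m, fams))
  expect_equal(as.vector(agg), c(4, 3))
  # singleton family passes through
  agg1 <- as.matrix(aggregate_families(m[1, , drop = FALSE],
                                       c(l1 = "SOLO")))
  expect_equal(as.vector(agg1), as.vector(m[1, ]))
  # mean is bounded by member loci for random inputs
  rnd <- with_seed(2, matrix(runif(60), 6,
                             dimnames = list(paste0("l", 1:6),
                                             paste0("s", 1:10))))
  fams2 <- setNames(rep(c("X", "Y"), each = 3), paste0("l", 1:6))
  agg2 <- as.matrix(aggregate_families(rnd, fams2))
  for (fam in c("X", "Y")) {
    mem <- rnd[names(fams2)[fams2 == fam], ]
    expect_true(all(agg2[fam, ] >= apply(mem, 2, min) - 1e-12))
    expect_true(all(agg2[fam, ] <= apply(mem, 2, max) + 1e-12))
  }
  expect_error(aggregate_families(m, c(l1 = "FAM", l2 = "FAM")),
               "locus without family")
})

test_that("log_zscale gives zero-mean unit-sd rows and zeroes constants", {
  m <- with_seed(3, matrix(rpois(50, 30), 5,
                           dimnames = list(paste0("f", 1:5),
                                           paste0("s", 1:10))))
  m[5, ] <- 7  # constant feature
  z <- as.matrix(log_zscale(m))
  expect_equal(unname(rowMeans(z[1:4, ])), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z[1:4, ], 1, sd)), rep(1, 4),
               tolerance = 1e-12)
  expect_true(all(z[5, ] == 0))
  # pseudocount 1 maps zero TPM to log value 0
  z0 <- log2(matrix(0, 1, 1) + 1)
  expect_equal(as.vector(z0), 0)
})

test_that("EM recovers proportions from simulated equivalence classes", {
  feats <- paste0("f", 1:10)
  props <- setNames(c(0.2, 0.15, 0.13, 0.12, 0.1, 0.09, 0.08, 0.06,
                      0.04, 0.03), feats)
  classes <- c(as.list(setNames(feats, paste0("u_", feats))),
               setNames(lapply(seq(1, 9, by = 2), function(i)
                 feats[c(i, i + 1)]), paste0("amb", 1:5)))
  w <- setNames(c(rep(1, 10), rep(0.25, 5)), names(classes))
  cls <- simulate_read_classes(props, classes, 1e5, seed = 21,
                               class_weights = w)
  # ~20% of reads land in ambiguous classes
  amb_mass <- sum(vapply(cls[11:15], `[[`, 0, "count")) / 1e5
  expect_equal(amb_mass, 0.2, tolerance = 0.02)
  fit <- em_quantify(cls, setNames(rep(1000, 10), feats))
  expect_lt(sum(abs(fit$theta - props)), 0.02)
})
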