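test_that("rare filter removes low-prevalence AND low-abundance ASVs", {
  ## 88 samples so the 5% threshold is 5 samples (paper's "4 samples
  ## overall" is ceiling(0.05 * 88) - 1 below threshold)
  set.seed(1)
  counts <- matrix(rpois(30 * 88, 5), 30, 88,
                   dimnames = list(sprintf("a%02d", 1:30),
                                   sprintf("s%02d", 1:88)))
  counts["a01", ] <- 0; counts["a01", 1:3] <- c(3, 3, 2)   # 3 samples, total 8
  counts["a02", ] <- 0; counts["a02", 1:50] <- 1           # prevalent, low total
  counts["a03", ] <- 0; counts["a03", 1:3] <- c(50, 50, 50) # rare, abundant
  meta <- data.frame(sample_id = colnames(counts),
                     subject = rep(sprintf("p%d", 1:8), length.out = 88),
                     day = rep(1:11, each = 8), diet = "FV",
                     phase = "outbound")
  tab <- LongitudinalASVTable(counts, meta)
  filt <- suppressMessages(filterRare(tab, 0.05, 10))
  expect_false("a01" %in% asvIds(filt))   # both conditions -> removed
  expect_true("a02" %in% asvIds(filt))    # prevalent -> kept
  expect_true("a03" %in% asvIds(filt))    # abundant -> kept
  expect_identical(S4Vectors::metadata(filt)$removed_asvs, "a01")
})

test_that("filter matches the per-ASV brute-force rule and is idempotent", {
  des <- smallDesign(n_stable_asvs = 40, n_transient_asvs = 160,
                     transient_mean_abundance = 1, depth_range = c(3000, 9000))
  tab <- generateSynthetic(des, seed = 9, tree = FALSE)
  cts <- SummarizedExperiment::assay(tab, "counts")
  keepOracle <- vapply(seq_len(nrow(cts)), function(i) {
    prevalent <- sum(cts[i, ] > 0) >= ceiling(0.05 * ncol(cts))
    abundant <- sum(cts[i, ]) >= 10
    prevalent || abundant
  }, TRUE)
  filt <- suppressMessages(filterRare(tab, 0.05, 10))
  expect_identical(asvIds(filt), rownames(cts)[keepOracle])
  again <- suppressMessages(filterRare(filt, 0.05, 10))
  expect_identical(asvIds(again), asvIds(filt))
})

test_that("size factors follow the median-of-ratios closed forms", {
  m <- matrix(c(10, 20, 5, 10, 40, 8), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m[, 2] <- m[, 1] * 2
  sf <- sizeFactors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  ## identical samples -> equal factors
  expect_equal(unname(sizeFactors(cbind(m[, 1], m[, 1]))), c(1, 1))
  ## rescaling by the factors equalizes ratios: recomputed factors ~ 1
  set.seed(4)
  big <- matrix(rnbinom(50 * 6, mu = 40, size = 5) + 1, 50, 6)
  dimnames(big) <- list(sprintf("a%d", 1:50), sprintf("s%d", 1:6))
  sf2 <- sizeFactors(big)
  rescaled <- sweep(big, 2, sf2, "/")
  expect_equal(unname(sizeFactors(rescaled)), rep(1, 6), tolerance = 1e-8)
  ## scale-equivariance: multiplying one sample by c multiplies its
  ## factor by c (ratios preserved after renormalization)
  big2 <- big; big2[, 3] <- big2[, 3] * 5
  sf3 <- sizeFactors(big2)
  expect_equal(unname(sf3[3] / sf3[1]), unname(5 * sf2[3] / sf2[1]),
               tolerance = 1e-8)
})

test_that("size factors agree with DESeq2 on an all-positive table", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  m <- matrix(rnbinom(80 * 5, mu = 60, size = 8) + 1, 80, 5)
  dimnames(m) <- list(sprintf("a%d", 1:80), sprintf("s%d", 1:5))
  ## with no zeros the positive-counts reference equals the classic one,
  ## so the factors match DESeq2's up to the geometric-mean rescaling
  ds <- DESeq2::estimateSizeFactorsForMatrix(m)
  ## DESeq2 takes the median in log-ratio space; with an even ASV count
  ## the two middle values average geometrically there, arithmetically
  ## here, so agreement is to ~1e-4, not machine precision
  expect_equal(unname(sizeFactors(m)),
               unname(ds / exp(mean(log(ds)))), tolerance = 1e-3)
})

test_that("wisconsin+sqrt matches hand computation and its identity", {
  m <- matrix(c(4, 4, 0, 8), nrow = 2,
              dimnames = list(c("a1", "a2"), c("s1", "s2")))
  ## rows: a1 = (4, 0), a2 = (4, 8)
  m["a1", ] <- c(4, 0); m["a2", ] <- c(4, 8)
  w <- wisconsinSqrt(m)
  expect_equal(unname(w), matrix(c(0.8165, 0.5774, 0, 1), 2),
               tolerance = 1e-4)
  ## single ASV: every nonzero sample maps to 1
  expect_equal(unname(wisconsinSqrt(matrix(c(3, 7, 0), 1)))[1, ],
               c(1, 1, 0))
  ## squared column sums are 1 for every nonzero column; zero rows stay 0
  set.seed(2)
  r <- matrix(rpois(60, 2), 6, 10)
  r[3, ] <- 0
  wr <- wisconsinSqrt(r)
  nz <- colSums(r) > 0
  expect_equal(unname(colSums(wr[, nz]^2)), rep(1, sum(nz)))
  expect_true(all(wr[3, ] == 0))
})

test_that("wisconsin+sqrt agrees with vegan on positive tables", {
  set.seed(3)
  m <- matrix(rpois(40, 8) + 1, 5, 8)
  v <- sqrt(t(vegan::wisconsin(t(m))))
  expect_equal(unname(wisconsinSqrt(m)), unname(unclass(v)[, ]),
               tolerance = 1e-12)
})
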