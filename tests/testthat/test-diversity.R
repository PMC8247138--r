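test_that("inverse Simpson matches direct summation", {
  expect_equal(inverseSimpson(c(10, 10, 10, 10)), 4)
  expect_equal(inverseSimpson(c(7, 0, 0)), 1)
  expect_equal(inverseSimpson(c(50, 30, 20)), 1 / (0.25 + 0.09 + 0.04))
  expect_error(inverseSimpson(c(0, 0)), "all-zero")
})

test_that("Good's coverage follows its formula and boundaries", {
  expect_equal(goodsCoverage(c(5, 10, 2)), 100)
  expect_equal(goodsCoverage(c(1, rep(200, 50), 9)), 100 * (1 - 1 / 10010))
  expect_equal(goodsCoverage(rep(1, 7)), 0)
  expect_error(goodsCoverage(c(1.5, 2)), "non-integer")
})

test_that("rarefaction curve matches boundaries and enumeration", {
  x <- c(5, 3, 2)
  expect_equal(unname(rarefactionCurve(x, sum(x))), 3)
  expect_equal(unname(rarefactionCurve(x, 1)), 1)
  ## exhaustive oracle at depth 2: all C(10, 2) read pairs
  reads <- rep(1:3, x)
  pairs <- combn(10, 2)
  oracle <- mean(apply(pairs, 2, function(p) length(unique(reads[p]))))
  expect_equal(unname(rarefactionCurve(x, 2)), oracle, tolerance = 1e-10)
  expect_error(rarefactionCurve(x, 11), "exceeds")
})

test_that("Sorensen dissimilarity and decomposition are exact", {
  expect_equal(as.numeric(sorensenDissimilarity(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(sorensenDissimilarity(c(1, 0), c(0, 2))), 1)
  ## A = 3, B = 4, J = 2 -> 3/7
  x <- c(1, 1, 1, 0, 0, 0); y <- c(1, 1, 0, 1, 1, 0)
  expect_equal(as.numeric(sorensenDissimilarity(x, y)), 3 / 7)
  dec <- attr(sorensenDissimilarity(x, y), "decomposition")
  expect_equal(dec$J, 2)
  expect_equal(dec$A, dec$J)    # presence/absence: similarity = shared
  expect_error(sorensenDissimilarity(c(0, 0), c(0, 0)), "empty")
})

test_that("Bray-Curtis two-formula identity and decomposition hold", {
  x <- c(1, 2, 0); y <- c(0, 2, 3)
  bc <- brayCurtisDissimilarity(x, y)
  expect_equal(as.numeric(bc), 0.5)
  dec <- attr(bc, "decomposition")
  expect_equal(dec$A, 2); expect_equal(dec$B, 1); expect_equal(dec$C, 3)
  expect_equal((dec$B + dec$C) / (2 * dec$A + dec$B + dec$C), 0.5)
  expect_equal(as.numeric(brayCurtisDissimilarity(x, x)), 0)
  expect_equal(as.numeric(brayCurtisDissimilarity(c(1, 0), c(0, 3))), 1)
  expect_error(brayCurtisDissimilarity(c(-1, 2, 0), y), "negative")
})

test_that("indexes satisfy metric-style properties on random pairs", {
  set.seed(10)
  for (i in 1:200) {
    x <- rpois(30, 3); y <- rpois(30, 3)
    if (sum(x) == 0 || sum(y) == 0) next
    for (f in list(brayCurtisDissimilarity, sorensenDissimilarity)) {
      d1 <- as.numeric(f(x, y)); d2 <- as.numeric(f(y, x))
      expect_identical(d1, d2)
      expect_true(d1 >= 0 && d1 <= 1)
    }
  }
})

test_that("UniFrac matches edge-by-edge enumeration on a 3-leaf tree", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  x <- c(A = 1, B = 0, C = 0); y <- c(A = 0, B = 1, C = 0)
  ## unique length 2 (A:1, B:1) of spanned 3 (internal edge shared)
  expect_equal(unifracDistance(x, y, tree, weighted = FALSE), 2 / 3)
  expect_equal(unifracDistance(x, x, tree, weighted = FALSE), 0)
  expect_equal(unifracDistance(x, x, tree, weighted = TRUE), 0)
  ## disjoint subtrees meeting at the root: unweighted = 1
  tree2 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  xs <- c(A = 1, B = 1, C = 0, D = 0); ys <- c(A = 0, B = 0, C = 1, D = 1)
  expect_equal(unifracDistance(xs, ys, tree2, weighted = FALSE), 1)
  expect_error(unifracDistance(c(A = 1, Z = 1, C = 0), c(A = 1, Z = 0, C = 1),
                               tree, weighted = FALSE), "Z")
})

test_that("unweighted UniFrac on a unit star tree collapses to the
           presence/absence (Jaccard) distance", {
  ## on a star tree with unit branches, unique branch length is b + c and
  ## the union spans a + b + c, i.e. the Jaccard distance 2S/(1 + S)
  ## where S is the Sorensen dissimilarity
  set.seed(6)
  nwk <- paste0("(", paste(sprintf("t%d:1", 1:12), collapse = ","), ");")
  star <- ape::read.tree(text = nwk)
  for (i in 1:20) {
    x <- rbinom(12, 1, 0.5); y <- rbinom(12, 1, 0.5)
    if (sum(x) == 0 || sum(y) == 0) next
    names(x) <- names(y) <- star$tip.label
    S <- as.numeric(sorensenDissimilarity(x, y))
    expect_equal(unifracDistance(x, y, star, weighted = FALSE),
                 2 * S / (1 + S), tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric, equivariant, and match the
           element operations", {
  set.seed(7)
  m <- matrix(rpois(8 * 5, 4), 8, 5,
              dimnames = list(sprintf("a%d", 1:8), sprintf("s%d", 1:5)))
  m[, 5] <- m[, 1]   # duplicate sample
  d <- distanceMatrix(m, "bray_curtis")
  expect_equal(d["s1", "s5"], 0)
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  ## element-op oracle over all pairs
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d[i, j],
                 as.numeric(brayCurtisDissimilarity(m[, i], m[, j])),
                 tolerance = 1e-12)
  ## permuting samples permutes rows/columns identically
  perm <- c(3, 1, 5, 2, 4)
  d2 <- distanceMatrix(m[, perm], "bray_curtis")
  expect_equal(unname(d2), unname(d[perm, perm]), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## sorensen path matches element op too
  ds <- distanceMatrix(m, "sorensen")
  expect_equal(ds["s2", "s3"],
               as.numeric(sorensenDissimilarity(m[, 2], m[, 3])),
               tolerance = 1e-12)
})

test_that("within-subject series uses consecutive pairs at the later day", {
  tab <- tinyTable()
  w <- withinSubjectSeries(tab, "bray_curtis", assay = "counts")
  pts <- seriesPoints(w)
  expect_equal(nrow(pts), 2)          # 2 subjects x 1 transition
  expect_true(all(pts$day == 100))    # later-day assignment
  cts <- SummarizedExperiment::assay(tab, "counts")
  expect_equal(pts$value[pts$subject == "s1"],
               as.numeric(brayCurtisDissimilarity(cts[, "s1_d1"],
                                                  cts[, "s1_d2"])))
  ## identical communities -> zero turnover
  cts2 <- cbind(cts[, c(1, 1, 3, 3)])
  colnames(cts2) <- colnames(cts)
  meta <- data.frame(sample_id = colnames(cts),
                     subject = c("s1", "s1", "s2", "s2"),
                     day = c(1, 100, 1, 100), diet = "FV",
                     phase = "outbound")
  tab2 <- LongitudinalASVTable(cts2, meta)
  w2 <- withinSubjectSeries(tab2, "bray_curtis", assay = "counts")
  expect_equal(seriesPoints(w2)$value, c(0, 0))
  ## 2 subjects x 3 timepoints -> exactly 4 points
  m3 <- matrix(rpois(18, 5) + 1, 3, 6)
  dimnames(m3) <- list(c("a", "b", "c"), sprintf("q%d", 1:6))
  meta3 <- data.frame(sample_id = colnames(m3),
                      subject = rep(c("u", "v"), each = 3),
                      day = rep(c(1, 50, 100), 2), diet = "FV",
                      phase = "outbound")
  w3 <- withinSubjectSeries(LongitudinalASVTable(m3, meta3),
                            "bray_curtis", assay = "counts")
  expect_equal(nrow(seriesPoints(w3)), 4)
})

test_that("between-subjects series averages pairwise distances per day", {
  m <- matrix(c(5, 0, 0, 5, 3, 3), 2, 3,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  meta <- data.frame(sample_id = c("x", "y", "z"),
                     subject = c("p", "q", "r"), day = 1, diet = "FV",
                     phase = "outbound")
  tab <- LongitudinalASVTable(m, meta)
  b <- betweenSubjectsSeries(tab, "bray_curtis", assay = "counts")
  pts <- seriesPoints(b)
  dd <- c(brayCurtisDissimilarity(m[, 1], m[, 2]),
          brayCurtisDissimilarity(m[, 1], m[, 3]),
          brayCurtisDissimilarity(m[, 2], m[, 3]))
  expect_equal(pts$value, mean(as.numeric(dd)))
  expect_identical(pts$subject, "ALL")
  ## identical subjects -> zero divergence
  m2 <- m; m2[, 2] <- m[, 1]; m2[, 3] <- m[, 1]
  b2 <- betweenSubjectsSeries(LongitudinalASVTable(m2, meta),
                              "bray_curtis", assay = "counts")
  expect_equal(seriesPoints(b2)$value, 0)
})
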