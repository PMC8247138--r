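test_that("persistence matrix matches the brute-force double loop", {
  tab <- generateSynthetic(smallDesign(), seed = 12, tree = FALSE)
  pm <- persistenceMatrix(tab, 2)
  cts <- SummarizedExperiment::assay(tab, "counts")
  days <- sort(unique(sampleDays(tab)))
  for (a in sample(rownames(pm), 12)) for (d in sample(days, 4)) {
    hits <- 0
    for (s in unique(subjects(tab))) {
      i <- which(subjects(tab) == s & sampleDays(tab) == d)
      if (length(i) && cts[a, i] >= 2) hits <- hits + 1
    }
    expect_identical(pm[a, as.character(d)], as.integer(hits))
  }
  ## bounded by subjects sampled that day
  expect_true(all(pm <= 6))
})

test_that("scaling centers rows and zeroes constant profiles", {
  pm <- rbind(rep(6L, 10), c(rep(0L, 9), 2L), rep(0L, 10))
  sc <- scalePersistence(pm)
  expect_equal(sc[1, ], rep(0, 10))          # constant row -> zeros
  expect_equal(sc[3, ], rep(0, 10))          # never detected -> zeros
  expect_equal(mean(sc[2, ]), 0, tolerance = 1e-12)
  expect_equal(sd(sc[2, ]), 1, tolerance = 1e-12)
})

test_that("DTW distance is a proper elastic distance", {
  expect_equal(dtwDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  ## one-step shifted copies: warping absorbs the offset, the rigid
  ## (lock-step) L1 distance does not
  a <- c(0, 0, 1, 5, 1, 0, 0, 0)
  b <- c(0, 0, 0, 1, 5, 1, 0, 0)
  expect_lt(dtwDistance(a, b), sum(abs(a - b)))
  ## matrix interface agrees with the pairwise op
  m <- rbind(a = a, b = b, c = rev(a))
  D <- dtwDistanceMatrix(m)
  expect_equal(D["a", "b"], dtwDistance(a, b))
  expect_identical(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("DTW clustering separates planted stable and transient ASVs", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:3, function(sd) {
    tab <- generateSynthetic(smallDesign(), seed = sd, tree = FALSE)
    truth <- S4Vectors::metadata(tab)$truth
    pm <- persistenceMatrix(tab, 1)
    cl <- dtwCluster(pm, 2)
    lab <- ifelse(rownames(pm) %in% truth$stable_asvs, 2, 1)
    mclust::adjustedRandIndex(cl$assignment$cluster, lab)
  }, 0)
  expect_gt(median(aris), 0.9)
  ## cluster 2 is by construction the higher-persistence cluster
  tab <- generateSynthetic(smallDesign(), seed = 1, tree = FALSE)
  cl <- dtwCluster(persistenceMatrix(tab, 1), 2)
  expect_gt(cl$summary$mean_persistence[2], cl$summary$mean_persistence[1])
  expect_error(dtwCluster(matrix(0, 1, 5), 2), "fewer")
})

test_that("persistence-abundance fit recovers exact and planted lines", {
  ## y = 2x exactly
  pm <- matrix(rep(0:5, each = 4), 6, 4, byrow = FALSE)
  rownames(pm) <- sprintf("a%d", 1:6)
  x <- rowMeans(pm) / 6
  m <- matrix(exp(2 * x) - 1, 6, 4,
              dimnames = list(rownames(pm), sprintf("s%d", 1:4)))
  meta <- data.frame(sample_id = colnames(m),
                     subject = c("p", "p", "q", "q"), day = c(1, 9, 1, 9),
                     diet = "FV", phase = "outbound")
  tab <- LongitudinalASVTable(round(m * 50 + 1), meta)
  SummarizedExperiment::assay(tab, "scaled") <- m
  fit <- persistenceAbundanceFit(pm, tab, nSubjects = 6)
  expect_equal(fit$b, 2, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  ## degenerate: identical persistence -> error
  pmc <- matrix(3, 6, 4, dimnames = dimnames(pm))
  expect_error(persistenceAbundanceFit(pmc, tab), "variance")
  ## planted coupling in the generator: positive slope, CI above 0
  gtab <- generateSynthetic(smallDesign(), seed = 4, tree = FALSE)
  gpm <- persistenceMatrix(suppressMessages(scaleCounts(gtab)), 1)
  gfit <- persistenceAbundanceFit(gpm, gtab)
  expect_gt(gfit$ci[1], 0)
  expect_gt(gfit$r2, 0.5)
})

test_that("networks mirror the persistence matrix and count snapshots", {
  tab <- generateSynthetic(smallDesign(), seed = 6, tree = FALSE)
  nets <- buildNetworks(tab, 1)
  pm <- persistenceMatrix(tab, 1)
  expect_equal(length(nets), length(unique(sampleDays(tab))))
  for (d in names(nets))                     # total edges = sum persistence
    expect_equal(nrow(nets[[d]]), sum(pm[, d]))
  deg <- degreeCentrality(nets)
  d1 <- deg[deg$day == as.numeric(names(nets)[1]), ]
  expect_equal(sum(d1$degree), nrow(nets[[1]]))
  expect_true(all(d1$degree >= 1))
})

test_that("edge deltas register single gains, losses, and conservation", {
  n1 <- data.frame(subject = c("p", "p"), asv = c("a", "b"))
  n2 <- data.frame(subject = c("p", "p", "p"), asv = c("a", "b", "c"))
  d <- edgeDeltas(list(`1` = n1, `10` = n2))
  expect_equal(d$formed, 1); expect_equal(d$destroyed, 0)
  dId <- edgeDeltas(list(`1` = n1, `10` = n1))
  expect_equal(dId$formed, 0); expect_equal(dId$destroyed, 0)
  ## bookkeeping identity on a full synthetic run
  tab <- generateSynthetic(smallDesign(), seed = 2, tree = FALSE)
  dd <- edgeDeltas(buildNetworks(tab, 1))
  expect_identical(dd$edges_after,
                   dd$edges_before + dd$formed - dd$destroyed)
})

test_that("formed and destroyed edges are uncorrelated under pure churn", {
  des <- syntheticDesign(n_subjects = 12, n_dropped_followup = 0,
                         n_stable_asvs = 50, walk_sd = 0.6,
                         planted_changepoints = numeric(),
                         segment_turnover_slopes = 0,
                         churn_decay = 0, postiso_formed_jump = 0,
                         n_driver_asvs = 0)
  ok <- vapply(1:10, function(sd) {
    tab <- generateSynthetic(des, seed = sd, tree = FALSE)
    abs(attr(edgeDeltas(buildNetworks(tab, 1)), "spearman")$rho) < 0.2
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("edge models recover planted jumps and trends", {
  ## no planted jump: indicator CI covers zero
  des0 <- smallDesign(postiso_formed_jump = 0, churn_decay = 0)
  tab0 <- generateSynthetic(des0, seed = 3, tree = FALSE)
  em0 <- suppressWarnings(edgeModels(edgeDeltas(buildNetworks(tab0, 1)), 520))
  co0 <- lmmCoef(em0$formed, "post_isolation")
  expect_true(abs(co0$b) <= qt(0.975, co0$df) * co0$SE)
  ## planted decay: negative day slope for formed edges
  desT <- smallDesign(churn_decay = 0.4, postiso_formed_jump = 0)
  negs <- vapply(1:5, function(sd) {
    tabT <- generateSynthetic(desT, seed = sd, tree = FALSE)
    emT <- suppressWarnings(
      edgeModels(edgeDeltas(buildNetworks(tabT, 1)), 520))
    lmmCoef(emT$formed, "day")$b < 0
  }, TRUE)
  expect_gte(sum(negs), 4)
})

test_that("stable cluster dominates centrality at every timepoint", {
  tab <- generateSynthetic(seed = 15, tree = FALSE)
  filt <- suppressMessages(filterRare(tab))
  pm <- persistenceMatrix(filt, 1)
  cl <- dtwCluster(pm, 2)
  nets <- buildNetworks(filt, 1)
  cmp <- clusterRankTests(degreeCentrality(nets), cl)
  expect_true(all(cmp$median_cluster2 > cmp$median_cluster1))
  expect_true(all(cmp$p < 0.01))
})
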