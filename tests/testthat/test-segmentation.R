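test_that("PELT stays quiet on i.i.d. series", {
  clean <- vapply(1:20, function(i) {
    set.seed(i)
    length(peltChangepoints(rnorm(100))) == 0
  }, TRUE)
  expect_gte(mean(clean), 0.9)
  expect_warning(peltChangepoints(c(1, 2, 3)), "short")
})

test_that("PELT pins a planted distributional step", {
  set.seed(7)
  y <- c(rnorm(30, 0, 0.1), rnorm(30, 5, 0.1))
  cps <- peltChangepoints(y)
  expect_length(cps, 1)
  expect_lte(abs(cps - 30), 1)
})

test_that("PELT equals the unpruned exhaustive optimum on short series", {
  set.seed(42)
  for (case in 1:30) {
    n <- sample(6:20, 1)
    y <- rnorm(n) + if (case %% 2) rep(c(0, 3), c(floor(n / 2),
                                                  ceiling(n / 2))) else 0
    got <- peltChangepoints(y)
    want <- oracleSegmentation(y)
    expect_equal(attr(got, "objective"), attr(want, "objective"),
                 tolerance = 1e-9)
    expect_identical(as.integer(got), as.integer(want))
  }
  ## and against full mask enumeration at tiny n
  set.seed(11)
  for (case in 1:6) {
    y <- rnorm(9) + rep(c(0, 2.5), c(4, 5))
    expect_equal(attr(peltChangepoints(y), "objective"),
                 attr(enumSegmentation(y), "objective"), tolerance = 1e-9)
  }
})

test_that("detections are invariant to strictly monotone transforms", {
  set.seed(13)
  y <- c(rnorm(25, 0, 0.3), rnorm(25, 4, 0.3))
  expect_identical(as.integer(peltChangepoints(y)),
                   as.integer(peltChangepoints(exp(y / 2))))
  expect_identical(as.integer(peltChangepoints(y)),
                   as.integer(peltChangepoints(rank(y))))
})

## shared fixture: one default-design series and its segmentation
withinFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- generateSynthetic(seed = 101, tree = FALSE)
      filt <- suppressMessages(scaleCounts(filterRare(scaleCounts(tab))))
      w <- withinSubjectSeries(filt, "bray_curtis")
      cfg <- analysisConfig(seed = 101)
      seg <- suppressWarnings(segmentSeries(w, cfg))
      cache <<- list(w = w, seg = seg, cfg = cfg)
    }
    cache
  }
})

test_that("GA fitness dominates both seeded masks", {
  fx <- withinFixture()
  pts <- seriesPoints(fx$w)
  allDays <- sort(unique(pts$day)); allDays <- head(allDays, -1)
  cands <- poolCandidates(fx$w)
  cache <- new.env(parent = emptyenv())
  fit <- function(days) microdyn:::maskFitness(
    allDays %in% days, allDays, pts, TRUE, 2, cache)
  expect_gte(fx$seg@fitness, fit(cands) - 1e-9)
  expect_gte(fx$seg@fitness, fit(numeric()) - 1e-9)
  ## trace is monotone non-decreasing (elitism)
  tr <- fx$seg@ga_trace$best_fitness
  expect_true(all(diff(tr) >= -1e-12))
})

test_that("a single-slope series is left unsegmented", {
  set.seed(30)
  days <- sort(unique(seriesPoints(withinFixture()$w)$day))
  pts <- do.call(rbind, lapply(sprintf("p%d", 1:6), function(s)
    data.frame(subject = s, day = days,
               value = 0.3 + 0.0004 * days + rnorm(length(days), 0, 0.02))))
  ser <- microdyn:::DiversitySeries("within_subject", "bray_curtis", pts)
  seg <- suppressWarnings(segmentSeries(ser, analysisConfig(seed = 1)))
  expect_length(changepointDays(seg), 0)
})

test_that("segment fits report Table-2 schema with day-based slopes", {
  fx <- withinFixture()
  fits <- suppressWarnings(fitSegments(fx$w, fx$seg))
  expect_named(fits, c("segment", "start_day", "end_day", "b", "SE", "t",
                       "df", "p", "cumulative_effect"))
  expect_equal(fits$cumulative_effect,
               fits$b * (fits$end_day - fits$start_day))
  ## a flat segment's slope CI covers zero
  set.seed(8)
  flat <- do.call(rbind, lapply(1:6, function(s)
    data.frame(subject = s, day = seq(10, 130, by = 10),
               value = 0.4 + rnorm(13, 0, 0.02))))
  serF <- microdyn:::DiversitySeries("within_subject", "bray_curtis", flat)
  segF <- microdyn:::Segmentation(numeric(), range(flat$day))
  ff <- suppressWarnings(fitSegments(serF, segF))
  expect_true(abs(ff$b) <= qt(0.975, ff$df) * ff$SE)
})

test_that("segmentOf uses end-inclusive boundaries", {
  seg <- microdyn:::Segmentation(c(123, 480), c(1, 720))
  expect_equal(segmentOf(seg, c(1, 123, 124, 480, 481, 720)),
               c(1, 1, 2, 2, 3, 3))
  tab <- segmentTable(seg)
  expect_equal(tab$start_day, c(1, 123, 480))
  expect_equal(tab$end_day, c(123, 480, 720))
})
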