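## Drivers of diversity: per-ASV trend models on standardized absolute
## consecutive differences, and hypergeometric enrichment of the stable
## cluster among each subject's drivers.

#' Per-ASV trend models for one subject
#'
#' For every ASV carried by the subject, the series of absolute
#' differences of normalized abundance at consecutive transitions
#' (assigned to the later day) is z-standardized and regressed on day with
#' segment-specific intercepts and slopes (segments from the global
#' within-subject segmentation). An ASV is a driver when the model is
#' significant (BH-adjusted overall F p < \code{alpha} across the
#' subject's ASVs) AND every segment slope sign matches the global
#' within-subject pattern.
#'
#' @param x a \linkS4class{LongitudinalASVTable} with a \code{"scaled"}
#'   assay (added on the fly if missing).
#' @param seg the global within-subject \linkS4class{Segmentation}.
#' @param subject subject id.
#' @param globalSigns sign pattern of the global per-segment slopes
#'   (from \code{\link{fitSegments}}); defaults taken from
#'   \code{attr(seg, "segment_signs")} if present.
#' @param alpha driver significance level (default 0.05).
#' @return data.frame of class \code{driverResult}: subject, asv_id,
#'   per-segment slopes (comma-joined), concordant, p, p_adj, driver.
#' @export
asvTrendModels <- function(x, seg, subject, globalSigns = NULL,
                           alpha = 0.05) {
  if (!"scaled" %in% SummarizedExperiment::assayNames(x))
    x <- scaleCounts(x)
  m <- SummarizedExperiment::assay(x, "scaled")
  idx <- which(subjects(x) == subject)
  if (!length(idx)) stop("unknown subject: ", subject)
  idx <- idx[order(sampleDays(x)[idx])]
  days <- sampleDays(x)[idx]
  if (length(idx) < 3) stop("subject has too few timepoints")
  transDays <- days[-1]
  segIdx <- segmentOf(seg, transDays)
  nSeg <- length(changepointDays(seg)) + 1
  rows <- lapply(rownames(m), function(a) {
    v <- m[a, idx]
    if (all(v == 0)) return(NULL)      # ASV absent from subject: skipped
    dv <- abs(diff(v))
    if (sd(dv) == 0)
      return(data.frame(subject = subject, asv_id = a,
                        slopes = NA_character_, concordant = FALSE,
                        p = 1, stringsAsFactors = FALSE))
    z <- as.numeric(scale(dv))
    d <- data.frame(z = z, day = transDays,
                    segment = factor(segIdx, levels = seq_len(nSeg)))
    fit <- if (nSeg > 1) lm(z ~ segment + segment:day, data = d)
           else lm(z ~ day, data = d)
    fs <- summary(fit)$fstatistic
    p <- if (is.null(fs)) 1 else
      unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    cf <- coef(fit)
    slopeNames <- if (nSeg > 1)
      paste0("segment", seq_len(nSeg), ":day") else "day"
    slopes <- unname(cf[slopeNames])
    data.frame(subject = subject, asv_id = a,
               slopes = paste(signif(slopes, 4), collapse = ","),
               concordant = !anyNA(slopes) && !is.null(globalSigns) &&
                 all(sign(slopes) == globalSigns),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p)
  out$driver <- out$p_adj < alpha & out$concordant
  class(out) <- c("driverResult", "data.frame")
  out
}

#' Driver analysis across all subjects
#'
#' Runs \code{\link{asvTrendModels}} per subject, deriving the global
#' sign pattern from the per-segment fits of the within-subject series.
#'
#' @param x a \code{LongitudinalASVTable} (filtered, scaled).
#' @param seg the global within-subject \linkS4class{Segmentation}.
#' @param segFits output of \code{\link{fitSegments}} for that
#'   segmentation (source of the global slope signs).
#' @param alpha driver significance level.
#' @return combined \code{driverResult} data.frame over all subjects.
#' @export
driverAnalysis <- function(x, seg, segFits, alpha = 0.05) {
  signs <- sign(segFits$b)
  out <- lapply(unique(subjects(x)), function(s)
    asvTrendModels(x, seg, s, globalSigns = signs, alpha = alpha))
  out <- do.call(rbind, out)
  class(out) <- c("driverResult", "data.frame")
  out
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric with population N, K successes and n
#' draws.
#'
#' @param k observed successes in the draw.
#' @param N population size.
#' @param K successes in the population.
#' @param n draw size.
#' @return probability in (0, 1].
#' @export
hypergeomUpperTail <- function(k, N, K, n) {
  stopifnot(k >= 0, K <= N, n <= N, k <= min(n, K))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Stable-cluster enrichment among drivers
#'
#' For each subject, tests whether its drivers of diversity
#' over-represent the stable cluster (cluster 2): upper-tail
#' hypergeometric with universe N = all clustered ASVs, K = stable-cluster
#' size, n = the subject's driver count, k = stable drivers. BH-adjusted
#' across subjects; fold enrichment = (k/n) / (K/N).
#'
#' @param drivers \code{driverResult} data.frame (all subjects).
#' @param clusters a \code{persistenceClusters} object covering the ASV
#'   universe.
#' @return data.frame of class \code{enrichmentResult}: subject, N, K, n,
#'   k, fold, p, p_adj.
#' @export
hypergeomEnrichment <- function(drivers, clusters) {
  lab <- setNames(clusters$assignment$cluster, clusters$assignment$asv_id)
  stableSet <- names(lab)[lab == max(lab)]
  N <- length(lab)
  K <- length(stableSet)
  out <- lapply(split(drivers, drivers$subject), function(d) {
    sel <- d$asv_id[d$driver]
    n <- length(sel)
    k <- sum(sel %in% stableSet)
    if (n == 0) {
      warning("no drivers for subject ", d$subject[1], "; p = 1")
      p <- 1; fold <- 0
    } else {
      p <- hypergeomUpperTail(k, N, K, n)
      fold <- (k / n) / (K / N)
    }
    data.frame(subject = d$subject[1], N = N, K = K, n = n, k = k,
               fold = fold, p = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$p_adj <- bhAdjust(out$p)
  class(out) <- c("enrichmentResult", "data.frame")
  out
}
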