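## Rare-ASV filtering, median-of-ratios depth normalization and the
## Wisconsin double standardization + square-root transform.

#' Filter rare ASVs
#'
#' Removes ASVs that BOTH occur in fewer than
#' \code{ceiling(prevalenceFraction * n_samples)} samples AND have total
#' abundance below \code{minAbundance}. Requiring both conditions targets
#' extremely rare taxa (which dominate qualitative indexes) without deleting
#' prevalent-but-low-count ASVs. Idempotent.
#'
#' @param x a \linkS4class{LongitudinalASVTable}.
#' @param prevalenceFraction fraction of samples in (0, 1].
#' @param minAbundance minimum total count.
#' @return the filtered table; removed ASV ids in
#'   \code{metadata(x)$removed_asvs}.
#' @export
filterRare <- function(x, prevalenceFraction = 0.05, minAbundance = 10) {
  stopifnot(prevalenceFraction > 0, prevalenceFraction <= 1)
  cts <- SummarizedExperiment::assay(x, "counts")
  minSamples <- ceiling(prevalenceFraction * ncol(cts))
  prev <- rowSums(cts > 0)
  tot <- rowSums(cts)
  drop <- prev < minSamples & tot < minAbundance
  if (all(drop)) stop("rare-ASV filter would remove every ASV")
  message(sum(drop), " of ", nrow(cts), " ASVs removed by rare filter (< ",
          minSamples, " samples and total abundance < ", minAbundance, ")")
  out <- x[!drop, ]
  S4Vectors::metadata(out)$removed_asvs <- rownames(cts)[drop]
  out
}

#' Median-of-ratios size factors (positive-counts reference)
#'
#' DESeq-style depth normalization adapted to zero-inflated amplicon tables:
#' the reference profile is the geometric mean of each ASV over the samples
#' where it is nonzero, and each sample's factor is the median of
#' count/reference over its nonzero ASVs. Factors are rescaled to geometric
#' mean 1, so they are equivariant: scaling one sample's counts by c scales
#' its factor by c (up to the common renormalization).
#'
#' @param x a \code{LongitudinalASVTable} or a count matrix (ASV x sample).
#' @return named vector of positive size factors, one per sample.
#' @export
sizeFactors <- function(x) {
  cts <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  if (any(colSums(cts) == 0)) stop("every sample needs a nonzero count")
  logc <- log(cts)
  logc[!is.finite(logc)] <- NA
  ref <- exp(rowMeans(logc, na.rm = TRUE))       # positive-counts geomean
  ratios <- cts / ref
  ratios[cts == 0] <- NA
  sf <- apply(ratios, 2, median, na.rm = TRUE)
  if (anyNA(sf) || any(!is.finite(sf)) || any(sf <= 0))
    stop("a sample shares no informative ASV with the reference profile")
  sf / exp(mean(log(sf)))
}

#' Scale counts by size factors
#'
#' Adds a \code{"scaled"} assay (counts divided column-wise by
#' \code{\link{sizeFactors}}) and stores the factors in \code{colData}.
#'
#' @param x a \linkS4class{LongitudinalASVTable}.
#' @return \code{x} with assay \code{"scaled"}.
#' @export
scaleCounts <- function(x) {
  sf <- sizeFactors(x)
  SummarizedExperiment::assay(x, "scaled") <-
    sweep(SummarizedExperiment::assay(x, "counts"), 2, sf, "/")
  SummarizedExperiment::colData(x)$size_factor <- sf
  x
}

#' Square root of the Wisconsin double standardization
#'
#' Each ASV row is divided by its row maximum, then each sample column by
#' its column sum, then the square root is taken elementwise. All-zero rows
#' or columns are left at zero.
#'
#' @param m non-negative numeric matrix (ASV x sample).
#' @return transformed matrix; squared column sums equal 1 for every
#'   nonzero column.
#' @export
wisconsinSqrt <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative values")
  rmax <- apply(m, 1, max)
  m <- m / ifelse(rmax > 0, rmax, 1)
  csum <- colSums(m)
  m <- sweep(m, 2, ifelse(csum > 0, csum, 1), "/")
  sqrt(m)
}

#' Add a transformed assay for beta-diversity computation
#'
#' \code{"wisconsin_sqrt"} applies \code{\link{wisconsinSqrt}} to the scaled
#' counts (used for Bray-Curtis and Sorensen); UniFrac uses the
#' \code{"scaled"} assay with the supplied tree.
#'
#' @param x a table that already carries a \code{"scaled"} assay (see
#'   \code{\link{scaleCounts}}).
#' @return \code{x} with assay \code{"wisconsin_sqrt"}.
#' @export
transformCounts <- function(x) {
  if (!"scaled" %in% SummarizedExperiment::assayNames(x))
    x <- scaleCounts(x)
  SummarizedExperiment::assay(x, "wisconsin_sqrt") <-
    wisconsinSqrt(SummarizedExperiment::assay(x, "scaled"))
  x
}
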