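## Alpha diversity, coverage/rarefaction, pairwise beta-diversity with
## gains/losses decomposition, distance matrices, and the temporal series
## (within-subject turnover, between-subject divergence).

#' Inverse Simpson index
#'
#' \eqn{1 / \sum p_i^2} with \eqn{p_i} the relative abundances; 1 for a
#' single-taxon sample, S for a uniform sample over S taxa.
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry (scaled counts are fine).
#' @return a real >= 1.
#' @export
inverseSimpson <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("all-zero sample")
  as.numeric(vegan::diversity(counts, index = "invsimpson"))
}

#' Good's coverage estimator
#'
#' \eqn{100 (1 - F_1 / N)} where \eqn{F_1} is the number of singleton ASVs
#' and N the total read count. Only defined on raw integer counts.
#'
#' @param counts integer count vector.
#' @return coverage percentage in [0, 100].
#' @export
goodsCoverage <- function(counts) {
  if (any(counts != round(counts)) || any(counts < 0))
    stop("coverage is undefined on non-integer counts")
  n <- sum(counts)
  if (n <= 0) stop("empty sample")
  100 * (1 - sum(counts == 1) / n)
}

#' Expected rarefaction curve
#'
#' Expected richness at each subsampling depth d:
#' \eqn{E[S_d] = \sum_i (1 - C(N - N_i, d) / C(N, d))}, computed through
#' log-gamma arithmetic (via \code{vegan::rarefy}).
#'
#' @param counts integer count vector.
#' @param depths integer depths, each <= sum(counts).
#' @return named numeric vector of expected richness per depth.
#' @export
rarefactionCurve <- function(counts, depths) {
  if (any(counts != round(counts)) || any(counts < 0))
    stop("rarefaction needs integer counts")
  n <- sum(counts)
  if (any(depths > n)) stop("depth exceeds sample total ", n)
  if (any(depths < 1)) stop("depths must be >= 1")
  out <- vapply(depths, function(d)
    as.numeric(vegan::rarefy(counts, sample = d)), 0)
  names(out) <- depths
  out
}

## shared gains/losses decomposition: A = unscaled similarity, B = losses
## from sample 1 to 2, C = gains, J = number of shared ASVs
bcDecomposition <- function(x, y, qualitative) {
  if (qualitative) {
    px <- x > 0; py <- y > 0
    J <- sum(px & py)
    list(A = J, B = sum(px & !py), C = sum(!px & py), J = J)
  } else {
    list(A = sum(pmin(x, y)), B = sum(pmax(0, x - y)),
         C = sum(pmax(0, y - x)), J = sum(x > 0 & y > 0))
  }
}

#' Sorensen dissimilarity with gains/losses decomposition
#'
#' \eqn{(A + B - 2J) / (A + B)} with A, B the richness of the two samples
#' and J the number of shared ASVs. The attached decomposition reports the
#' qualitative similarity/loss/gain components (similarity = J).
#'
#' @param x,y abundance or presence vectors of equal length.
#' @return dissimilarity in [0, 1]; components in attribute
#'   \code{"decomposition"}.
#' @export
sorensenDissimilarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  a <- sum(x > 0); b <- sum(y > 0)
  if (a + b == 0) stop("both samples are empty")
  dec <- bcDecomposition(x, y, qualitative = TRUE)
  structure((a + b - 2 * dec$J) / (a + b), decomposition = dec)
}

#' Bray-Curtis dissimilarity with gains/losses decomposition
#'
#' \eqn{\sum_j |x_j - y_j| / \sum_j (x_j + y_j)}; identically
#' \eqn{(B + C) / (2A + B + C)} with A the shared (minimum) abundance,
#' B the abundance losses and C the gains.
#'
#' @param x,y non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in [0, 1]; components in attribute
#'   \code{"decomposition"}.
#' @export
brayCurtisDissimilarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  tot <- sum(x + y)
  if (tot == 0) stop("both samples are empty")
  dec <- bcDecomposition(x, y, qualitative = FALSE)
  structure(sum(abs(x - y)) / tot, decomposition = dec)
}

## build a two-or-more sample phyloseq object pruned to the table's ASVs
unifracMatrix <- function(m, tree, weighted) {
  miss <- setdiff(rownames(m)[rowSums(m) > 0], tree$tip.label)
  if (length(miss))
    stop("ASV(s) missing from the tree: ", paste(head(miss, 5),
                                                 collapse = ", "))
  extra <- setdiff(tree$tip.label, rownames(m))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(m[tree$tip.label, , drop = FALSE],
                        taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  ## suppressWarnings: phyloseq's edge-matrix fill warns harmlessly on
  ## multifurcating (e.g. star) trees
  as.matrix(suppressWarnings(
    phyloseq::UniFrac(ps, weighted = weighted, normalized = TRUE,
                      parallel = FALSE)))
}

#' UniFrac distance between two samples
#'
#' Unweighted: branch length unique to either sample's leaf set divided by
#' the total branch length spanned by the union. Weighted: normalized
#' abundance-weighted branch-length difference (range [0, 1]).
#'
#' @param x,y abundance vectors named by ASV id (or unnamed, matching
#'   \code{tree$tip.label} order).
#' @param tree rooted \code{phylo} tree whose leaves cover the nonzero ASVs.
#' @param weighted logical.
#' @return distance in [0, 1].
#' @export
unifracDistance <- function(x, y, tree, weighted = FALSE) {
  nm <- names(x)
  if (is.null(nm)) nm <- tree$tip.label[seq_along(x)]
  m <- cbind(s1 = x, s2 = y)
  rownames(m) <- nm
  unifracMatrix(m, tree, weighted)["s1", "s2"]
}

#' Pairwise distance matrix for a community table
#'
#' @param m numeric matrix, ASVs x samples (use the transformed assay
#'   appropriate for the index).
#' @param index one of \code{"sorensen"}, \code{"bray_curtis"},
#'   \code{"unweighted_unifrac"}, \code{"weighted_unifrac"}.
#' @param tree rooted phylogeny (UniFrac indexes only).
#' @return symmetric matrix with zero diagonal and attribute
#'   \code{"index_name"}.
#' @export
distanceMatrix <- function(m, index = c("bray_curtis", "sorensen",
                                        "unweighted_unifrac",
                                        "weighted_unifrac"), tree = NULL) {
  index <- match.arg(index)
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least two samples")
  d <- switch(index,
    bray_curtis = as.matrix(vegan::vegdist(t(m), method = "bray")),
    sorensen = as.matrix(vegan::vegdist(t(m), method = "bray",
                                        binary = TRUE)),
    unweighted_unifrac = {
      if (is.null(tree)) stop("UniFrac needs a tree")
      unifracMatrix(m, tree, weighted = FALSE)
    },
    weighted_unifrac = {
      if (is.null(tree)) stop("UniFrac needs a tree")
      unifracMatrix(m, tree, weighted = TRUE)
    })
  diag(d) <- 0
  structure(d, index_name = index)
}

indexAssay <- function(index) {
  if (index %in% c("bray_curtis", "sorensen")) "wisconsin_sqrt" else "scaled"
}

pairwiseFor <- function(index, tree) {
  switch(index,
    bray_curtis = function(x, y) as.numeric(brayCurtisDissimilarity(x, y)),
    sorensen = function(x, y) as.numeric(sorensenDissimilarity(x, y)),
    unweighted_unifrac = function(x, y)
      unifracDistance(x, y, tree, weighted = FALSE),
    weighted_unifrac = function(x, y)
      unifracDistance(x, y, tree, weighted = TRUE),
    stop("unknown index: ", index))
}

#' Within-subject turnover series
#'
#' For each subject and each consecutive-timepoint transition, the chosen
#' dissimilarity between the two samples, assigned to the later day (so the
#' isolation-end effect lines up with post-isolation transitions). Subjects
#' with a single timepoint are excluded with a warning.
#'
#' @param x a \linkS4class{LongitudinalASVTable}; the \code{"scaled"}
#'   assay is used when present (falling back to raw counts), or the
#'   assay named by \code{assay}.
#' @param index dissimilarity index.
#' @param tree phylogeny for UniFrac indexes.
#' @param assay assay name override.
#' @return a \linkS4class{DiversitySeries} of kind \code{"within_subject"}.
#' @export
withinSubjectSeries <- function(x, index = "bray_curtis", tree = NULL,
                                assay = NULL) {
  m <- seriesAssay(x, index, assay)
  cd <- SummarizedExperiment::colData(x)
  fn <- pairwiseFor(index, tree)
  pts <- lapply(unique(cd$subject), function(s) {
    idx <- which(cd$subject == s)
    idx <- idx[order(cd$day[idx])]
    if (length(idx) < 2) {
      warning("subject ", s, " has a single timepoint; excluded")
      return(NULL)
    }
    vals <- vapply(seq_len(length(idx) - 1), function(k)
      fn(m[, idx[k]], m[, idx[k + 1]]), 0)
    data.frame(subject = s, day = cd$day[idx][-1], value = vals)
  })
  DiversitySeries("within_subject", index, do.call(rbind, pts))
}

#' Between-subjects divergence series
#'
#' For each timepoint, the mean of all pairwise dissimilarities among the
#' subjects sampled that day. Timepoints with fewer than two subjects are
#' excluded with a warning.
#'
#' @inheritParams withinSubjectSeries
#' @return a \linkS4class{DiversitySeries} of kind \code{"between_subjects"}.
#' @export
betweenSubjectsSeries <- function(x, index = "bray_curtis", tree = NULL,
                                  assay = NULL) {
  m <- seriesAssay(x, index, assay)
  cd <- SummarizedExperiment::colData(x)
  fn <- pairwiseFor(index, tree)
  pts <- lapply(sort(unique(cd$day)), function(d) {
    idx <- which(cd$day == d)
    if (length(idx) < 2) {
      warning("day ", d, " has a single subject; excluded")
      return(NULL)
    }
    pairs <- combn(idx, 2)
    vals <- vapply(seq_len(ncol(pairs)), function(k)
      fn(m[, pairs[1, k]], m[, pairs[2, k]]), 0)
    data.frame(subject = "ALL", day = d, value = mean(vals))
  })
  DiversitySeries("between_subjects", index, do.call(rbind, pts))
}

## Turnover series default to size-factor-scaled counts: the Wisconsin
## row-maximum standardization used for ordination gives every ASV equal
## weight, so a quantitative turnover series computed on it would be
## dominated by sporadic low-count ASVs.
seriesAssay <- function(x, index, assay) {
  if (is.null(assay)) {
    assay <- if ("scaled" %in% SummarizedExperiment::assayNames(x))
      "scaled" else "counts"
  }
  SummarizedExperiment::assay(x, assay)
}

#' Alpha-diversity table (inverse Simpson per sample)
#'
#' Computed on size-factor-scaled counts of the unfiltered table, one row
#' per sample with its subject/day/diet/isolation annotation.
#'
#' @param x a \code{LongitudinalASVTable} (scaled on the fly if needed).
#' @return data.frame with columns sample_id, subject, day, diet, phase,
#'   in_isolation, value.
#' @export
alphaDiversity <- function(x) {
  if (!"scaled" %in% SummarizedExperiment::assayNames(x)) x <- scaleCounts(x)
  m <- SummarizedExperiment::assay(x, "scaled")
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = colnames(m), subject = cd$subject, day = cd$day,
             diet = cd$diet, phase = cd$phase,
             in_isolation = cd$in_isolation,
             value = apply(m, 2, inverseSimpson), row.names = NULL)
}
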