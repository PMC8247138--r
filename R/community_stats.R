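## Ordination, PERMANOVA, dispersion homogeneity, one-way ANOVA and BH
## correction. All heavy lifting is delegated to vegan / stats; this layer
## fixes the interface, seeds, and the reported schemas.

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimization with monotone regression, best of
#' \code{nStarts} random starts (vegan's \code{metaMDS} engine on a
#' precomputed distance matrix, so no internal transform or rescaling of
#' the data is involved).
#'
#' @param d distance matrix (square matrix or \code{dist}).
#' @param k embedding dimension (default 2).
#' @param nStarts random starts (default 300).
#' @param seed RNG seed for the starts.
#' @return list of class \code{nmdsResult}: \code{coordinates}
#'   (samples x k), \code{stress}, \code{converged}, \code{n_starts}.
#' @export
runNMDS <- function(d, k = 2, nStarts = 300, seed = 1L) {
  dd <- as.dist(d)
  n <- attr(dd, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  set.seed(seedFor(seed, "nmds"))
  fit <- vegan::metaMDS(dd, k = k, try = nStarts, trymax = nStarts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  structure(list(coordinates = fit$points, stress = fit$stress,
                 converged = isTRUE(fit$converged) || fit$converged > 0,
                 n_starts = nStarts, model = fit), class = "nmdsResult")
}

#' @export
print.nmdsResult <- function(x, ...) {
  cat("nMDS:", ncol(x$coordinates), "dimensions, stress =",
      format(x$stress, digits = 4), "\n")
  invisible(x)
}

#' Permutational multivariate analysis of variance
#'
#' Sequential (Type I) sums of squares on the Gower-centered inner-product
#' matrix, in the stated factor order, with unrestricted row permutations
#' (vegan's \code{adonis2}, \code{by = "terms"}). Factor order matters:
#' put subject first for repeated-measures designs so its variance is
#' absorbed before diet and time. The unrestricted permutation scheme
#' ignores the repeated-measures structure; treat p-values for
#' time-varying factors as approximate.
#'
#' @param d distance matrix (square matrix or \code{dist}).
#' @param data data.frame of sample-level factors, rows aligned with
#'   \code{d}.
#' @param factors character vector of column names, in testing order.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return data.frame of class \code{permanovaResult}: term, df, sum_sq,
#'   r2, f, p (terms, then Residual and Total rows).
#' @export
runPermanova <- function(d, data, factors, nPerm = 1000, seed = 1L) {
  stopifnot(all(factors %in% colnames(data)))
  for (f in factors)
    if (length(unique(data[[f]])) < 2)
      stop("constant factor: ", f)
  dd <- as.dist(d)
  set.seed(seedFor(seed, "permanova"))
  form <- as.formula(paste("dd ~", paste(factors, collapse = " + ")))
  tab <- vegan::adonis2(form, data = data, permutations = nPerm,
                        by = "terms")
  out <- data.frame(term = rownames(tab), df = tab$Df, sum_sq = tab$SumOfSqs,
                    r2 = tab$R2, f = tab$F, p = tab$`Pr(>F)`,
                    row.names = NULL)
  class(out) <- c("permanovaResult", "data.frame")
  attr(out, "n_permutations") <- nPerm
  out
}

#' Multivariate dispersion homogeneity
#'
#' Principal-coordinate embedding with negative-eigenvalue correction,
#' per-sample distance to the group spatial median, and a one-way F test
#' on those distances (vegan's \code{betadisper} + \code{anova}).
#'
#' @param d distance matrix (square matrix or \code{dist}).
#' @param groups group label per sample.
#' @param center \code{"median"} (spatial median, default) or
#'   \code{"centroid"}.
#' @return list of class \code{dispersionResult}: \code{group_means}
#'   (mean distance-to-center per group), \code{F}, \code{p},
#'   \code{distances}, \code{model}.
#' @export
runBetadisper <- function(d, groups, center = c("median", "centroid")) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two members")
  bd <- vegan::betadisper(as.dist(d), groups, type = center)
  an <- anova(bd)
  structure(list(group_means = tapply(bd$distances, groups, mean),
                 F = an$`F value`[1], p = an$`Pr(>F)`[1],
                 distances = bd$distances, model = bd),
            class = "dispersionResult")
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition (used for alpha diversity by
#' subject, diet or isolation status).
#'
#' @param values numeric response.
#' @param groups group label per value.
#' @return list: \code{F}, \code{p}, \code{df} (between, within),
#'   \code{ss_between}, \code{ss_within}.
#' @export
anovaOneway <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  tab <- summary(aov(values ~ groups))[[1]]
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = tab$Df, ss_between = tab$`Sum Sq`[1],
       ss_within = tab$`Sum Sq`[2])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. Errors on out-of-range input rather than coercing.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
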