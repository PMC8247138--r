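## Persistence matrix, DTW clustering into stable vs. inconsistent
## microbiota, persistence-abundance regression, bipartite subject-ASV
## networks, edge turnover and centrality.

#' ASV persistence matrix
#'
#' Entry (a, t) is the number of subjects in which ASV a was detected
#' (count >= \code{threshold}) at timepoint day t.
#'
#' @param x a \linkS4class{LongitudinalASVTable} (typically the filtered
#'   table: filtering already removed sub-detection noise).
#' @param threshold detection threshold in reads (default 1).
#' @return integer matrix, ASVs x days (column names are the days).
#' @export
persistenceMatrix <- function(x, threshold = 1) {
  stopifnot(threshold >= 1)
  cts <- SummarizedExperiment::assay(x, "counts")
  det <- cts >= threshold
  days <- sort(unique(sampleDays(x)))
  pm <- sapply(days, function(d)
    rowSums(det[, sampleDays(x) == d, drop = FALSE]))
  colnames(pm) <- days
  storage.mode(pm) <- "integer"
  pm
}

#' Center and scale persistence profiles
#'
#' Subtracts each ASV's mean persistence and divides by its standard
#' deviation; constant rows become all-zero rather than NaN.
#'
#' @param pm a persistence matrix.
#' @return real matrix of the same shape.
#' @export
scalePersistence <- function(pm) {
  mu <- rowMeans(pm)
  sdv <- apply(pm, 1, sd)
  out <- (pm - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  out
}

#' DTW distance between two equally long series
#' @param a,b numeric vectors.
#' @return the dynamic time warping distance (symmetric step pattern, L1
#'   local cost, unconstrained window).
#' @export
dtwDistance <- function(a, b) .dtwSingle(as.numeric(a), as.numeric(b))

#' Pairwise DTW distances between matrix rows
#' @param m numeric matrix; each row is a time series.
#' @return symmetric distance matrix with row/col names of \code{m}.
#' @export
dtwDistanceMatrix <- function(m) {
  m <- as.matrix(m)
  D <- .dtwPairwise(m)
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

#' Cluster ASVs by persistence profile (DTW + PAM)
#'
#' Scales/centers the persistence profiles, computes pairwise DTW
#' distances and partitions them around medoids. Labels are mapped so that
#' cluster 2 is the one with the higher mean raw persistence ("stable
#' microbiota"), cluster 1 the lower ("inconsistent microbiota").
#'
#' @param pm raw persistence matrix (see \code{\link{persistenceMatrix}}).
#' @param k number of clusters (default 2).
#' @param seed kept for interface symmetry; PAM with BUILD initialization
#'   is deterministic.
#' @return list of class \code{persistenceClusters}: \code{assignment}
#'   (data.frame asv_id, cluster), \code{summary} (per cluster: size, mean
#'   persistence, with cluster k = highest persistence), \code{medoids}.
#' @export
dtwCluster <- function(pm, k = 2, seed = NULL) {
  if (nrow(pm) < k) stop("fewer ASVs than clusters")
  sc <- scalePersistence(pm)
  D <- dtwDistanceMatrix(sc)
  pam <- cluster::pam(as.dist(D), k = k, cluster.only = FALSE)
  raw <- pam$clustering
  meanPers <- tapply(rowMeans(pm), raw, mean)
  relabel <- rank(meanPers, ties.method = "first")  # 1 = least persistent
  clusterLab <- as.integer(relabel[as.character(raw)])
  assignment <- data.frame(asv_id = rownames(pm), cluster = clusterLab,
                           row.names = NULL)
  smry <- data.frame(
    cluster = sort(unique(clusterLab)),
    size = as.integer(table(clusterLab)),
    mean_persistence = as.numeric(tapply(rowMeans(pm), clusterLab, mean)))
  structure(list(assignment = assignment, summary = smry,
                 medoids = rownames(pm)[pam$id.med]),
            class = "persistenceClusters")
}

#' @export
print.persistenceClusters <- function(x, ...) {
  cat("Persistence clustering (DTW + PAM):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Persistence-abundance regression
#'
#' Ordinary least squares of log mean normalized abundance on mean
#' persistence (expressed as a fraction of subjects): the classic
#' occupancy-abundance relationship.
#'
#' @param pm persistence matrix.
#' @param x the matching \code{LongitudinalASVTable} (scaled assay used,
#'   computed on the fly if absent).
#' @param nSubjects number of subjects (defaults to those present in
#'   \code{x}).
#' @return list: \code{b} (slope), \code{ci} (95\% confidence interval),
#'   \code{r2}, \code{t}, \code{df}, \code{p}, and the underlying
#'   \code{model}.
#' @export
persistenceAbundanceFit <- function(pm, x, nSubjects = NULL) {
  if (nrow(pm) < 3) stop("need at least three ASVs")
  if (!"scaled" %in% SummarizedExperiment::assayNames(x))
    x <- scaleCounts(x)
  if (is.null(nSubjects)) nSubjects <- length(unique(subjects(x)))
  m <- SummarizedExperiment::assay(x, "scaled")[rownames(pm), ,
                                                drop = FALSE]
  df <- data.frame(persistence = rowMeans(pm) / nSubjects,
                   log_abundance = log(rowMeans(m) + 1))
  if (var(df$persistence) == 0)
    stop("no persistence variance across ASVs")
  fit <- lm(log_abundance ~ persistence, data = df)
  s <- coef(summary(fit))["persistence", ]
  list(b = unname(s[1]), ci = unname(confint(fit)["persistence", ]),
       r2 = summary(fit)$r.squared, t = unname(s[3]),
       df = fit$df.residual, p = unname(s[4]), model = fit)
}

#' Bipartite subject-ASV network snapshots
#'
#' One snapshot per timepoint; an edge (subject, asv) exists iff the ASV
#' was detected (count >= threshold) in that subject's sample that day.
#'
#' @inheritParams persistenceMatrix
#' @return named list (by day) of data.frames with columns \code{subject},
#'   \code{asv}.
#' @export
buildNetworks <- function(x, threshold = 1) {
  cts <- SummarizedExperiment::assay(x, "counts")
  days <- sort(unique(sampleDays(x)))
  nets <- lapply(days, function(d) {
    idx <- which(sampleDays(x) == d)
    do.call(rbind, lapply(idx, function(i) {
      hit <- which(cts[, i] >= threshold)
      if (!length(hit)) return(NULL)
      data.frame(subject = subjects(x)[i], asv = rownames(cts)[hit],
                 row.names = NULL)
    }))
  })
  names(nets) <- days
  nets
}

#' Formed / destroyed edge counts per subject transition
#'
#' For each subject and consecutive pair of snapshots: formed = edges
#' present now but absent before, destroyed = the reverse. The attribute
#' \code{"spearman"} carries the Spearman correlation (and p-value)
#' between formed and destroyed counts over all transitions.
#'
#' @param nets snapshot list from \code{\link{buildNetworks}}.
#' @return data.frame: subject, day (of the transition's later timepoint),
#'   formed, destroyed, edges_before, edges_after.
#' @export
edgeDeltas <- function(nets) {
  if (length(nets) < 2) stop("need at least two snapshots")
  days <- as.numeric(names(nets))
  subj <- sort(unique(unlist(lapply(nets, function(n) n$subject))))
  out <- list()
  for (k in seq_len(length(nets) - 1)) {
    a <- nets[[k]]; b <- nets[[k + 1]]
    for (s in subj) {
      ea <- a$asv[a$subject == s]
      eb <- b$asv[b$subject == s]
      ## subjects absent from either snapshot (no sample) are skipped
      if (!s %in% a$subject || !s %in% b$subject) next
      out[[length(out) + 1]] <- data.frame(
        subject = s, day = days[k + 1],
        formed = length(setdiff(eb, ea)),
        destroyed = length(setdiff(ea, eb)),
        edges_before = length(ea), edges_after = length(eb))
    }
  }
  out <- do.call(rbind, out)
  sp <- tryCatch(suppressWarnings(
    cor.test(out$formed, out$destroyed, method = "spearman")),
    error = function(e) list(estimate = NA_real_, p.value = NA_real_))
  structure(out, spearman = list(rho = unname(sp$estimate),
                                 p = sp$p.value))
}

#' Mixed models for edge turnover
#'
#' Fits formed ~ day + post_isolation and destroyed ~ day +
#' post_isolation, each with subject random intercepts; the
#' post-isolation indicator captures the level shift at the end of the
#' isolation period (acquired/lost ASVs per transition).
#'
#' @param deltas output of \code{\link{edgeDeltas}}.
#' @param isolationEnd last day of isolation (default 520).
#' @return list with \code{lmmFit}s \code{formed} and \code{destroyed}.
#' @export
edgeModels <- function(deltas, isolationEnd = 520) {
  deltas$post_isolation <- as.integer(deltas$day > isolationEnd)
  list(formed = fitLMM(transform(deltas, value = formed),
                       value ~ day + post_isolation, "subject"),
       destroyed = fitLMM(transform(deltas, value = destroyed),
                          value ~ day + post_isolation, "subject"))
}

#' Per-ASV degree centrality over time
#'
#' Degree of each ASV node (number of subjects linked) per snapshot,
#' optionally normalized by the number of subjects sampled that day.
#'
#' @param nets snapshot list from \code{\link{buildNetworks}}.
#' @param normalized divide by subjects present that day.
#' @return data.frame: day, asv, degree.
#' @export
degreeCentrality <- function(nets, normalized = FALSE) {
  out <- lapply(names(nets), function(d) {
    n <- nets[[d]]
    if (is.null(n) || !nrow(n))
      return(NULL)
    deg <- table(n$asv)
    norm <- if (normalized) length(unique(n$subject)) else 1
    data.frame(day = as.numeric(d), asv = names(deg),
               degree = as.numeric(deg) / norm, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Per-timepoint rank-sum comparison of two ASV clusters
#'
#' Two-sided Wilcoxon rank-sum test of a per-ASV quantity (centrality,
#' abundance) between cluster 2 (stable) and cluster 1 (inconsistent) at
#' each timepoint. ASVs absent from a snapshot count as zeros.
#'
#' @param values data.frame with columns day, asv and the tested column.
#' @param clusters a \code{persistenceClusters} object.
#' @param column name of the tested column (default \code{"degree"}).
#' @return data.frame: day, median_cluster1, median_cluster2, p.
#' @export
clusterRankTests <- function(values, clusters, column = "degree") {
  lab <- setNames(clusters$assignment$cluster, clusters$assignment$asv_id)
  out <- lapply(split(values, values$day), function(d) {
    v <- setNames(d[[column]], d$asv)
    full <- setNames(rep(0, length(lab)), names(lab))
    full[names(v)[names(v) %in% names(full)]] <-
      v[names(v) %in% names(full)]
    g1 <- full[lab == 1]; g2 <- full[lab == 2]
    wt <- suppressWarnings(wilcox.test(g2, g1))
    data.frame(day = d$day[1], median_cluster1 = median(g1),
               median_cluster2 = median(g2), p = wt$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$day), ]
}
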