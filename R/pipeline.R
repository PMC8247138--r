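## End-to-end orchestration: generate/load -> preprocess -> diversity ->
## community stats -> segmentation -> persistence/networks -> drivers,
## with TSV outputs and a JSON run manifest.

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full longitudinal analysis pipeline
#'
#' Executes every stage in order and writes each stage's tables under
#' \code{outdir}: the (possibly synthetic) counts and metadata, the filter
#' report, alpha diversity and its trend, the distance matrix, nMDS
#' coordinates, PERMANOVA and dispersion tables, the within/between
#' turnover series, the segmentation (change-points, per-segment
#' coefficient table, GA trace), persistence clusters,
#' persistence-abundance fit, network edge lists, edge deltas and edge
#' models, drivers and enrichment, plus \code{manifest.json} echoing the
#' configuration, seed and output hashes. Any stage error aborts the run
#' naming the stage.
#'
#' @param config an \code{\link{analysisConfig}}.
#' @param countsPath,metadataPath input TSVs (ignored when
#'   \code{synthetic} is TRUE).
#' @param treePath optional Newick file (UniFrac indexes only).
#' @param synthetic generate the input table from \code{design} instead of
#'   reading files.
#' @param design a \code{\link{syntheticDesign}} (synthetic mode).
#' @param outdir output directory, created if needed.
#' @return invisibly, the manifest list; all results are also returned in
#'   the \code{results} element.
#' @export
runPipeline <- function(config = analysisConfig(), countsPath = NULL,
                        metadataPath = NULL, treePath = NULL,
                        synthetic = is.null(countsPath),
                        design = syntheticDesign(),
                        outdir = tempfile("microdyn_run_")) {
  if (!synthetic && (is.null(countsPath) || is.null(metadataPath)))
    stop("config error: provide counts and metadata paths or synthetic")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tree <- NULL
  if (synthetic) {
    tab <- stage("generate", generateSynthetic(design, seed = config$seed))
    tree <- S4Vectors::metadata(tab)$tree
    writeCountTable(tab, file.path(outdir, "counts.tsv"),
                    file.path(outdir, "metadata.tsv"))
    if (!is.null(tree))
      writeNewickTree(tree, file.path(outdir, "tree.nwk"))
  } else {
    tab <- stage("read", readCountTable(countsPath, metadataPath))
    if (!is.null(treePath)) tree <- readNewickTree(treePath)
  }

  ## preprocess: alpha diversity uses unfiltered scaled counts; the rare
  ## filter applies before beta diversity only
  tabScaled <- stage("preprocess", scaleCounts(tab))
  alpha <- stage("alpha", alphaDiversity(tabScaled))
  writeTsv(alpha, file.path(outdir, "alpha_diversity.tsv"))
  alphaTrend <- stage("alpha_trend", fitAlphaTrend(alpha))
  writeTsv(alphaTrend$coefficients,
           file.path(outdir, "alpha_trend.tsv"))

  filt <- stage("filter",
                filterRare(tabScaled, config$prevalence_fraction,
                           config$min_abundance))
  writeTsv(data.frame(removed_asv =
                        S4Vectors::metadata(filt)$removed_asvs),
           file.path(outdir, "filter_report.tsv"))
  filt <- stage("transform", transformCounts(scaleCounts(filt)))

  idx <- config$index
  mat <- SummarizedExperiment::assay(filt, indexAssay(idx))
  d <- stage("distance", distanceMatrix(mat, idx, tree = tree))
  writeTsv(data.frame(sample_id = rownames(d), d, check.names = FALSE),
           file.path(outdir, "distance_matrix.tsv"))

  cd <- as.data.frame(SummarizedExperiment::colData(filt))
  stats <- stage("community_stats", {
    nm <- runNMDS(d, k = 2, nStarts = config$nmds_starts,
                  seed = config$seed)
    pa <- runPermanova(d, cd, c("subject", "diet", "day"),
                       nPerm = config$n_permutations, seed = config$seed)
    bd <- lapply(c("subject", "diet", "phase"), function(f)
      data.frame(factor = f,
                 F = runBetadisper(d, cd[[f]])$F,
                 p = runBetadisper(d, cd[[f]])$p))
    list(nmds = nm, permanova = pa, betadisper = do.call(rbind, bd))
  })
  writeTsv(data.frame(sample_id = rownames(stats$nmds$coordinates),
                      stats$nmds$coordinates),
           file.path(outdir, "nmds_coordinates.tsv"))
  writeTsv(stats$permanova, file.path(outdir, "permanova.tsv"))
  writeTsv(stats$betadisper, file.path(outdir, "betadisper.tsv"))

  seg <- stage("segmentation", {
    within <- withinSubjectSeries(filt, idx, tree = tree)
    between <- betweenSubjectsSeries(filt, idx, tree = tree)
    segW <- segmentSeries(within, config)
    segB <- segmentSeries(between, config)
    list(within = within, between = between, segW = segW, segB = segB,
         fitsW = fitSegments(within, segW),
         fitsB = fitSegments(between, segB))
  })
  writeTsv(seriesPoints(seg$within),
           file.path(outdir, "within_subject_series.tsv"))
  writeTsv(seriesPoints(seg$between),
           file.path(outdir, "between_subjects_series.tsv"))
  writeTsv(seg$fitsW, file.path(outdir, "segments_within.tsv"))
  writeTsv(seg$fitsB, file.path(outdir, "segments_between.tsv"))
  writeTsv(seg$segW@ga_trace, file.path(outdir, "ga_trace_within.tsv"))
  writeTsv(data.frame(changepoint_day = changepointDays(seg$segW)),
           file.path(outdir, "changepoints_within.tsv"))

  pers <- stage("persistence", {
    pm <- persistenceMatrix(filt, config$detection_threshold)
    cl <- dtwCluster(pm, k = config$cluster_k, seed = config$seed)
    pa <- persistenceAbundanceFit(pm, filt)
    nets <- buildNetworks(filt, config$detection_threshold)
    deltas <- edgeDeltas(nets)
    em <- edgeModels(deltas, isolationEnd(filt))
    cent <- degreeCentrality(nets)
    list(pm = pm, clusters = cl, fit = pa, nets = nets, deltas = deltas,
         edge_models = em, centrality = cent)
  })
  writeTsv(pers$clusters$assignment,
           file.path(outdir, "persistence_clusters.tsv"))
  writeTsv(as.data.frame(pers$deltas),
           file.path(outdir, "edge_deltas.tsv"))
  writeTsv(pers$edge_models$formed$coefficients,
           file.path(outdir, "edge_model_formed.tsv"))
  writeTsv(pers$edge_models$destroyed$coefficients,
           file.path(outdir, "edge_model_destroyed.tsv"))
  edgeList <- do.call(rbind, lapply(names(pers$nets), function(d)
    cbind(day = d, pers$nets[[d]])))
  writeTsv(edgeList, file.path(outdir, "network_edges.tsv"))

  drv <- stage("drivers", {
    dd <- driverAnalysis(filt, seg$segW, seg$fitsW, alpha = config$alpha)
    en <- hypergeomEnrichment(dd, pers$clusters)
    list(drivers = dd, enrichment = en)
  })
  writeTsv(as.data.frame(drv$drivers), file.path(outdir, "drivers.tsv"))
  writeTsv(as.data.frame(drv$enrichment),
           file.path(outdir, "enrichment.tsv"))

  files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("microdyn")),
    config = unclass(config), seed = config$seed,
    synthetic = synthetic,
    outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$results <- list(table = tab, filtered = filt, alpha = alpha,
                           alpha_trend = alphaTrend, distance = d,
                           stats = stats, segmentation = seg,
                           persistence = pers, drivers = drv,
                           outdir = outdir)
  invisible(manifest)
}
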