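## TSV / Newick I/O, analysis configuration and seed plumbing.

#' Read an ASV count table and its sample metadata
#'
#' The counts TSV has ASVs as rows with a first column \code{asv_id} and one
#' column per sample; the metadata TSV has columns \code{sample_id},
#' \code{subject}, \code{day}, \code{diet}, \code{phase}. Every count column
#' must have a metadata row; violations are hard errors naming the offending
#' sample or matrix coordinate, never silent coercions.
#'
#' @param countsPath path to the counts TSV.
#' @param metadataPath path to the metadata TSV.
#' @param isolationEnd last day of isolation (default 520).
#' @return a \linkS4class{LongitudinalASVTable}, samples sorted by
#'   (subject, day).
#' @export
readCountTable <- function(countsPath, metadataPath, isolationEnd = 520) {
  if (!file.exists(countsPath)) stop("counts file not found: ", countsPath)
  if (!file.exists(metadataPath))
    stop("metadata file not found: ", metadataPath)
  raw <- read.delim(countsPath, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (colnames(raw)[1] != "asv_id")
    stop("first column of the counts TSV must be 'asv_id'")
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- raw$asv_id
  meta <- read.delim(metadataPath, stringsAsFactors = FALSE)
  LongitudinalASVTable(counts, meta, isolationEnd = isolationEnd)
}

#' Write a LongitudinalASVTable as counts + metadata TSVs
#'
#' @param x a \linkS4class{LongitudinalASVTable}.
#' @param countsPath,metadataPath output paths.
#' @return invisibly, the two paths.
#' @export
writeCountTable <- function(x, countsPath, metadataPath) {
  cts <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(asv_id = rownames(cts), cts, check.names = FALSE)
  write.table(df, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(x)
  meta <- data.frame(sample_id = rownames(cd), subject = cd$subject,
                     day = cd$day, diet = cd$diet, phase = cd$phase)
  write.table(meta, metadataPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(countsPath, metadataPath))
}

#' Read a rooted phylogeny over ASVs from a Newick file
#'
#' Missing branch lengths default to zero with a warning (they then
#' contribute nothing to UniFrac). Leaves absent from a count table are
#' tolerated here and pruned lazily at UniFrac time.
#'
#' @param path Newick file path.
#' @return an \code{ape} \code{phylo} tree.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree in ", path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Write a phylogeny to Newick
#' @param tree a \code{phylo} object.
#' @param path output path.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Analysis configuration
#'
#' One flat configuration drives the whole pipeline; every stochastic stage
#' draws its own substream seed deterministically from the master seed (see
#' \code{\link{seedFor}}), so reruns are reproducible.
#'
#' @param prevalence_fraction,min_abundance rare-ASV filter thresholds: an
#'   ASV is removed when it occurs in fewer than
#'   \code{ceiling(prevalence_fraction * n_samples)} samples AND has total
#'   abundance below \code{min_abundance}.
#' @param n_permutations permutations for PERMANOVA.
#' @param ga_population,ga_generations,ga_run,ga_pcrossover,ga_pmutation,ga_elitism
#'   genetic-algorithm hyperparameters (population size, generation cap,
#'   stagnation stop, uniform-crossover and per-bit mutation probabilities,
#'   elite fraction).
#' @param cluster_k number of persistence clusters (2: inconsistent/stable).
#' @param detection_threshold minimum count for an ASV to count as detected
#'   in a sample (persistence/network edge rule).
#' @param min_segment_transitions minimum average number of observed
#'   transitions per subject a segment must contain to be admissible.
#' @param alpha significance level.
#' @param index dissimilarity index for the turnover series.
#' @param nmds_starts random starts for nMDS.
#' @param seed master random seed.
#' @return a validated list of class \code{analysisConfig}.
#' @export
analysisConfig <- function(prevalence_fraction = 0.05, min_abundance = 10,
                           n_permutations = 1000, ga_population = 200,
                           ga_generations = 100, ga_run = 30,
                           ga_pcrossover = 0.8, ga_pmutation = 0.1,
                           ga_elitism = 0.05, cluster_k = 2,
                           detection_threshold = 1,
                           min_segment_transitions = 2, alpha = 0.05,
                           index = "bray_curtis", nmds_starts = 300,
                           seed = 1L) {
  cfg <- list(prevalence_fraction = prevalence_fraction,
              min_abundance = min_abundance,
              n_permutations = as.integer(n_permutations),
              ga_population = as.integer(ga_population),
              ga_generations = as.integer(ga_generations),
              ga_run = as.integer(ga_run), ga_pcrossover = ga_pcrossover,
              ga_pmutation = ga_pmutation, ga_elitism = ga_elitism,
              cluster_k = as.integer(cluster_k),
              detection_threshold = as.integer(detection_threshold),
              min_segment_transitions = min_segment_transitions,
              alpha = alpha, index = index,
              nmds_starts = as.integer(nmds_starts), seed = as.integer(seed))
  counts <- c("n_permutations", "ga_population", "ga_generations", "ga_run",
              "cluster_k", "detection_threshold", "nmds_starts")
  for (f in counts)
    if (cfg[[f]] <= 0) stop(f, " must be a positive count")
  rates <- c("prevalence_fraction", "ga_pcrossover", "ga_pmutation",
             "ga_elitism", "alpha")
  for (f in rates)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$prevalence_fraction == 0) stop("prevalence_fraction must be > 0")
  if (!cfg$index %in% c("sorensen", "bray_curtis", "unweighted_unifrac",
                        "weighted_unifrac"))
    stop("unknown index: ", cfg$index)
  structure(cfg, class = "analysisConfig")
}

#' Read / write a flat key=value configuration file
#' @param path config file path (lines of \code{key = value}; \code{#}
#'   comments allowed).
#' @return an \code{analysisConfig}.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v)) p[2] else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(analysisConfig, vals)
}

#' @rdname readAnalysisConfig
#' @param config an \code{analysisConfig}.
#' @export
writeAnalysisConfig <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Deterministic substream seed for a named stage
#'
#' Hashes the stage name into an offset added to the master seed, so every
#' stochastic stage gets its own reproducible stream and stages stay
#' decoupled (adding a stage never shifts another stage's stream).
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
seedFor <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}
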